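#' @name aucBD-accessors
#' @title Accessors for aucBD classes
#'
#' @description Slot accessors for the core S4 classes. `counts()` returns
#' the raw particle-count matrix, `profileValues()` the normalized c/c0
#' matrix, `radii()` and `scanTimes()` the grid, `geometry()` the cell,
#' `provenance()` the generating engine, and `molarMass()` the molar mass
#' recovered by an equilibrium fit.
#'
#' @param object an aucBD S4 object.
#' @return The slot value; see the class documentation for units.
NULL

#' @rdname aucBD-accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname aucBD-accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname aucBD-accessors
#' @export
setGeneric("scanTimes", function(object) standardGeneric("scanTimes"))

#' @rdname aucBD-accessors
#' @export
setGeneric("radii", function(object) standardGeneric("radii"))

#' @rdname aucBD-accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))

#' @rdname aucBD-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname aucBD-accessors
#' @export
setGeneric("molarMass", function(object) standardGeneric("molarMass"))

#' @rdname aucBD-accessors
#' @export
setMethod("counts", "CountMatrix", function(object) object@counts)

#' @rdname aucBD-accessors
#' @export
setMethod("geometry", "CountMatrix", function(object) object@geometry)

#' @rdname aucBD-accessors
#' @export
setMethod("scanTimes", "CountMatrix", function(object) object@scanTimes)

#' @rdname aucBD-accessors
#' @export
setMethod("scanTimes", "ConcentrationProfile", function(object) object@times)

#' @rdname aucBD-accessors
#' @export
setMethod("scanTimes", "RunConditions", function(object)
  seq_len(object@nScans) * object@tRun / object@nScans)

#' @rdname aucBD-accessors
#' @export
setMethod("radii", "ConcentrationProfile", function(object) object@radii)

#' @rdname aucBD-accessors
#' @export
setMethod("profileValues", "ConcentrationProfile",
          function(object) object@values)

#' @rdname aucBD-accessors
#' @export
setMethod("provenance", "ConcentrationProfile",
          function(object) object@provenance)

#' @rdname aucBD-accessors
#' @export
setMethod("molarMass", "EquilibriumFit", function(object) object@mFit)

#' @rdname aucBD-accessors
#' @export
setMethod("molarMass", "SoluteProperties", function(object) object@M)

setMethod("show", "PhysicalConstants", function(object) {
  cat("PhysicalConstants (CGS): R =", format(object@gasR, digits = 6),
      "erg/(mol K), T =", object@temperature, "K\n")
})

setMethod("show", "SoluteProperties", function(object) {
  cat(sprintf(
    "SoluteProperties '%s': s = %.3g S, D = %.3g cm^2/s, M = %.4g g/mol, 1-vbar*rho = %.3g\n",
    object@name, object@s * 1e13, object@D, object@M, object@buoyancy))
})

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf(
    "CellGeometry: [%.3f, %.3f] cm, phi = %.4f rad, h = %.2f cm, %d slices (chi = %.4g cm)\n",
    object@rMeniscus, object@rBottom, object@phi, object@height,
    object@nRadial, sliceWidth(object)))
})

setMethod("show", "RunConditions", function(object) {
  cat(sprintf(
    "RunConditions: %g rpm, tRun = %g s, %d steps, %d scans, %d particles, seed %d\n",
    object@rpm, object@tRun, object@nSteps, object@nScans,
    object@nParticles, object@seed))
})

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf(
    "CountMatrix: %d slices x %d scans, %d particles, t in [%g, %g] s\n",
    nrow(object@counts), ncol(object@counts), object@nParticles,
    min(object@scanTimes), max(object@scanTimes)))
})

setMethod("show", "ConcentrationProfile", function(object) {
  cat(sprintf(
    "ConcentrationProfile [%s]: %d radii x %d scans, c/c0 in [%.3g, %.3g]\n",
    object@provenance, length(object@radii), length(object@times),
    min(object@values), max(object@values)))
})

setMethod("show", "EquilibriumFit", function(object) {
  cat(sprintf(
    "EquilibriumFit: M = %.4g g/mol (slope %.4g cm^-2, %d points, RMS %.3g)\n",
    object@mFit, object@slope, object@nPoints, object@residualRMS))
  cat(sprintf("  window [%.3f, %.3f] cm; last-scan change %.3g\n",
              object@window[1], object@window[2], object@convergence))
})

setMethod("show", "RunSpec", function(object) {
  cat(sprintf("RunSpec: mode = %s, solute = '%s', %g rpm, tRun = %g s\n",
              object@mode, object@solute@name, object@run@rpm,
              object@run@tRun))
})
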