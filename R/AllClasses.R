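#' Physical constants in CGS units
#'
#' Container for the gas constant, Boltzmann constant, Avogadro's number and
#' the absolute temperature, all in CGS units (erg, g, cm, s). The internal
#' unit system of the whole package is CGS; sedimentation coefficients are
#' accepted in Svedberg (1 S = 1e-13 s) at the user-facing constructors and
#' stored in seconds.
#'
#' @slot kB Boltzmann constant (erg K^-1).
#' @slot nAvogadro Avogadro's number (mol^-1).
#' @slot gasR gas constant (erg mol^-1 K^-1); equals `kB * nAvogadro`.
#' @slot temperature absolute temperature (K).
#'
#' @seealso [physicalConstants()]
#' @export
setClass("PhysicalConstants",
  representation(kB = "numeric", nAvogadro = "numeric",
                 gasR = "numeric", temperature = "numeric"))

setValidity("PhysicalConstants", function(object) {
  msg <- character()
  if (length(object@temperature) != 1 || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive number (K)")
  if (abs(object@gasR - object@kB * object@nAvogadro) >
      1e-6 * abs(object@gasR))
    msg <- c(msg, "gasR must equal kB * nAvogadro (rel. tol. 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Hydrodynamic properties of one solute species
#'
#' Sedimentation coefficient, diffusion coefficient, molar mass and buoyancy
#' factor of a single non-interacting solute. The sedimentation coefficient
#' is stored in seconds; construct with [soluteProperties()], which accepts
#' Svedberg.
#'
#' @slot name species label.
#' @slot s sedimentation coefficient (seconds; 1 Svedberg = 1e-13 s).
#' @slot D diffusion coefficient (cm^2 s^-1).
#' @slot M molar mass (g mol^-1).
#' @slot buoyancy dimensionless buoyancy factor 1 - vbar*rho.
#' @slot friction translational friction coefficient (g s^-1), `NA` unless
#'   derived from `D` via the Einstein relation at construction.
#'
#' @seealso [soluteProperties()], [aucPreset()]
#' @export
setClass("SoluteProperties",
  representation(name = "character", s = "numeric", D = "numeric",
                 M = "numeric", buoyancy = "numeric", friction = "numeric"))

setValidity("SoluteProperties", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x)
  if (!num1(object@s) || object@s < 0)
    msg <- c(msg, "s must be a single non-negative number (seconds)")
  if (!num1(object@D) || object@D < 0)
    msg <- c(msg, "D must be a single non-negative number (cm^2/s)")
  if (!num1(object@M) || object@M < 0)
    msg <- c(msg, "M must be a single non-negative number (g/mol)")
  if (!num1(object@buoyancy) || object@buoyancy <= 0 || object@buoyancy > 1)
    msg <- c(msg, "buoyancy factor 1 - vbar*rho must lie in (0, 1]")
  if (length(object@friction) == 1 && !is.na(object@friction) &&
      object@friction <= 0)
    msg <- c(msg, "friction coefficient must be positive when given")
  if (length(msg)) msg else TRUE
})

#' Sector-cell geometry
#'
#' Geometry of the sector-shaped ultracentrifuge cell: meniscus and bottom
#' radii, sector angle, height, and the radial discretization used when
#' binning particles into concentration profiles. The slice width is
#' `chi = (rBottom - rMeniscus) / nRadial`; slices are half-open intervals
#' `[rMeniscus + (i-1)*chi, rMeniscus + i*chi)` with the bottom radius
#' assigned to the last slice, and the slice radius is the bin center.
#'
#' @slot rMeniscus meniscus radius (cm, distance from the rotor axis).
#' @slot rBottom bottom radius (cm).
#' @slot phi sector angle (rad). Cancels in all normalized outputs.
#' @slot height cell height (cm). Cancels in all normalized outputs.
#' @slot nRadial number of radial slices.
#'
#' @seealso [cellGeometry()], [sliceWidth()], [binRadii()]
#' @export
setClass("CellGeometry",
  representation(rMeniscus = "numeric", rBottom = "numeric", phi = "numeric",
                 height = "numeric", nRadial = "integer"))

setValidity("CellGeometry", function(object) {
  msg <- character()
  if (!(object@rMeniscus > 0))
    msg <- c(msg, "rMeniscus must be positive")
  if (!(object@rBottom > object@rMeniscus))
    msg <- c(msg, "rBottom must exceed rMeniscus")
  if (!(object@phi > 0)) msg <- c(msg, "sector angle phi must be positive")
  if (!(object@height > 0)) msg <- c(msg, "height must be positive")
  if (length(object@nRadial) != 1 || is.na(object@nRadial) ||
      object@nRadial < 2L)
    msg <- c(msg, "nRadial must be an integer >= 2")
  if (length(msg)) msg else TRUE
})

#' Run conditions of a simulated AUC experiment
#'
#' Rotor speed, total run time, and the discretization of the run into
#' Brownian-dynamics steps and recorded scans. The BD step is
#' `tRun / nSteps` and the scan interval `tau = tRun / nScans`; `nSteps`
#' must be a multiple of `nScans` so that every scan time is a step time.
#'
#' @slot rpm rotor speed (revolutions per minute).
#' @slot tRun total experiment time (s).
#' @slot nSteps number of BD steps per trajectory.
#' @slot nScans number of recorded scans, at times `t_j = j * tau`.
#' @slot nParticles number of independent particles.
#' @slot seed global random seed; particle `k`'s variates depend only on
#'   `(seed, k)`.
#'
#' @seealso [runConditions()], [simulateCounts()]
#' @export
setClass("RunConditions",
  representation(rpm = "numeric", tRun = "numeric", nSteps = "integer",
                 nScans = "integer", nParticles = "integer", seed = "integer"))

setValidity("RunConditions", function(object) {
  msg <- character()
  if (!(object@rpm >= 0)) msg <- c(msg, "rpm must be non-negative")
  if (!(object@tRun > 0)) msg <- c(msg, "tRun must be positive")
  if (is.na(object@nScans) || object@nScans < 1L)
    msg <- c(msg, "nScans must be >= 1")
  if (is.na(object@nSteps) || object@nSteps < object@nScans)
    msg <- c(msg, "nSteps must be >= nScans")
  else if (object@nSteps %% object@nScans != 0L)
    msg <- c(msg, "nSteps must be divisible by nScans")
  if (is.na(object@nParticles) || object@nParticles < 1L)
    msg <- c(msg, "nParticles must be >= 1")
  if (is.na(object@seed)) msg <- c(msg, "seed must be an integer")
  if (length(msg)) msg else TRUE
})

#' Particle counts per radial slice and scan
#'
#' The raw output of the Brownian-dynamics engine: an `nRadial x nScans`
#' integer matrix `n(i, j)` counting the particles found in radial slice `i`
#' at scan time `t_j`. Since no particle can leave the cell, every column
#' sums to the number of particles.
#'
#' @slot counts integer matrix, slices in rows, scans in columns.
#' @slot geometry the [CellGeometry-class] the counts were binned on.
#' @slot scanTimes scan times `t_j` (s), one per column.
#' @slot nParticles number of simulated particles.
#'
#' @seealso [simulateCounts()], [countsToConcentration()]
#' @export
setClass("CountMatrix",
  representation(counts = "matrix", geometry = "CellGeometry",
                 scanTimes = "numeric", nParticles = "integer"))

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (nrow(object@counts) != object@geometry@nRadial)
    msg <- c(msg, "counts must have nRadial rows")
  if (ncol(object@counts) != length(object@scanTimes))
    msg <- c(msg, "counts must have one column per scan time")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  cs <- colSums(object@counts)
  if (any(abs(cs - object@nParticles) > 1e-9 * object@nParticles))
    msg <- c(msg, "every scan column must sum to nParticles (conservation)")
  if (length(msg)) msg else TRUE
})

#' Normalized concentration profile c(r, t) / c0
#'
#' A concentration surface on an (r, t) grid, normalized by the loading
#' concentration. Produced by binning BD trajectories
#' ([countsToConcentration()]), by the Lamm-equation solver ([lammSolve()]),
#' or in closed form at sedimentation equilibrium
#' ([equilibriumProfileAnalytic()]).
#'
#' @slot radii bin-center radii (cm), strictly increasing.
#' @slot times scan times (s), one per column of `values`.
#' @slot values matrix of c/c0, radii in rows, scans in columns.
#' @slot provenance which engine produced the profile: `"BD"`, `"Lamm"` or
#'   `"analytic"`.
#' @slot c0 loading concentration (arbitrary units; 1 by default).
#' @slot rpm rotor speed (rpm) the profile was generated at, `NA` if unknown.
#'
#' @seealso [profileDistance()], [massBalance()], [writeProfile()]
#' @export
setClass("ConcentrationProfile",
  representation(radii = "numeric", times = "numeric", values = "matrix",
                 provenance = "character", c0 = "numeric", rpm = "numeric"))

setValidity("ConcentrationProfile", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@radii))
    msg <- c(msg, "values must have one row per radius")
  if (ncol(object@values) != length(object@times))
    msg <- c(msg, "values must have one column per time")
  if (length(object@radii) && any(diff(object@radii) <= 0))
    msg <- c(msg, "radii must be strictly increasing")
  if (any(object@values < -1e-8))
    msg <- c(msg, "concentrations must be non-negative")
  if (!(object@c0 > 0)) msg <- c(msg, "c0 must be positive")
  if (length(msg)) msg else TRUE
})

#' Result of the linearized sedimentation-equilibrium fit
#'
#' Ordinary least squares of `ln c(r)` against `r^2 - rMeniscus^2` over the
#' interior of the cell; the slope equals `omega^2 M (1 - vbar rho) / (2 R T)`,
#' from which the molar mass is recovered.
#'
#' @slot mFit recovered molar mass (g mol^-1).
#' @slot slope fitted slope (cm^-2).
#' @slot intercept fitted intercept, `ln(c(rMeniscus)/c0)` extrapolated.
#' @slot window radial fit window (cm), length 2.
#' @slot nPoints number of bins entering the fit.
#' @slot residualRMS root-mean-square residual of the fit in log space.
#' @slot convergence max |change in c/c0| between the last two scans of the
#'   fitted profile (`NA` when the profile holds a single scan); a
#'   diagnostic of approach to equilibrium, reported but not enforced.
#'
#' @seealso [fitEquilibriumMass()]
#' @export
setClass("EquilibriumFit",
  representation(mFit = "numeric", slope = "numeric", intercept = "numeric",
                 window = "numeric", nPoints = "integer",
                 residualRMS = "numeric", convergence = "numeric"))

setValidity("EquilibriumFit", function(object) {
  msg <- character()
  if (length(object@window) != 2 || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be an increasing radius interval")
  if (is.na(object@nPoints) || object@nPoints < 3L)
    msg <- c(msg, "a fit needs at least 3 points")
  if (length(msg)) msg else TRUE
})

#' Validated specification of one simulated experiment
#'
#' A complete, validated description of a run: mode, solute, cell geometry,
#' run conditions, analysis options and output location. Built from a flat
#' `key = value` configuration file and/or overrides by [readRunSpec()] /
#' [runSpec()], and executed by [runAUC()].
#'
#' @slot mode `"velocity"` or `"equilibrium"`.
#' @slot solute a [SoluteProperties-class].
#' @slot geometry a [CellGeometry-class].
#' @slot run a [RunConditions-class].
#' @slot temperature absolute temperature (K).
#' @slot exclusion terminal exclusion, as a fraction of the column length
#'   discarded at each end in comparisons and equilibrium fits.
#' @slot workers number of worker processes for particle simulation
#'   (numerically irrelevant by the partition contract).
#' @slot outDir output directory.
#' @slot preset preset name the spec was resolved from, or `""`.
#'
#' @seealso [readRunSpec()], [runAUC()]
#' @export
setClass("RunSpec",
  representation(mode = "character", solute = "SoluteProperties",
                 geometry = "CellGeometry", run = "RunConditions",
                 temperature = "numeric", exclusion = "numeric",
                 workers = "integer", outDir = "character",
                 preset = "character"))

setValidity("RunSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("velocity", "equilibrium"))
    msg <- c(msg, "mode must be 'velocity' or 'equilibrium'")
  if (!(object@temperature > 0)) msg <- c(msg, "temperature must be positive")
  if (object@exclusion < 0 || object@exclusion >= 0.5)
    msg <- c(msg, "exclusion fraction must lie in [0, 0.5)")
  if (is.na(object@workers) || object@workers < 1L)
    msg <- c(msg, "workers must be >= 1")
  if (length(msg)) msg else TRUE
})
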