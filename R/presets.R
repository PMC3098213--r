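# Reference solutes spanning a wide range of s/D, with the published run
# conditions for both experiment modes. Values as printed in the source
# literature compilations; the gamma-cyclodextrin molar mass is retained as
# printed even though it is not exactly Svedberg-consistent with its s and D.
.presetTable <- list(
  cyclodextrin = list(
    label = "gamma-cyclodextrin",
    s = 0.53, D = 27.0e-7, M = 1.50e3, buoyancy = 0.333,
    velocity = c(rpm = 55000, tRun = 40000),
    equilibrium = c(rpm = 30000, tRun = 300000)),
  lysozyme = list(
    label = "lysozyme",
    s = 1.89, D = 10.8e-7, M = 14.3e3, buoyancy = 0.298,
    velocity = c(rpm = 40000, tRun = 40000),
    equilibrium = c(rpm = 15000, tRun = 500000)),
  peo = list(
    label = "poly(ethylene oxide)",
    s = 2.30, D = 1.10e-7, M = 300e3, buoyancy = 0.170,
    velocity = c(rpm = 40000, tRun = 40000),
    equilibrium = c(rpm = 5000, tRun = 500000)),
  dna_t7 = list(
    label = "T7 DNA",
    s = 31.8, D = 0.066e-7, M = 26000e3, buoyancy = 0.450,
    velocity = c(rpm = 10000, tRun = 60000),
    equilibrium = NULL)
)

#' Built-in reference solutes
#'
#' Four solutes covering an extremely wide range of the
#' sedimentation-to-diffusion ratio: gamma-cyclodextrin (a small sugar),
#' lysozyme (a small globular protein), poly(ethylene oxide) (a flexible
#' polymer) and T7 bacteriophage DNA (a very long stiff chain). Each preset
#' carries the literature s (Svedberg), D (cm^2/s), M (g/mol) and buoyancy
#' factor, plus the standard rotor speed and duration for
#' sedimentation-velocity and (except T7 DNA) sedimentation-equilibrium
#' runs.
#'
#' @param name one of `aucPresets()`.
#' @param mode which run conditions to attach.
#' @param nParticles,nSteps,nScans,seed run discretization defaults,
#'   see [runConditions()].
#' @return `aucPresets()`: the preset names. `aucPreset()`: a list with
#'   elements `solute` (a [SoluteProperties-class]) and `run` (a
#'   [RunConditions-class] for the requested mode, or `NULL` if the preset
#'   has no conditions for that mode).
#' @examples
#' aucPresets()
#' aucPreset("lysozyme", "equilibrium")$run
#' @export
aucPreset <- function(name, mode = c("velocity", "equilibrium"),
                      nParticles = 1e5, nSteps = 50L, nScans = 50L,
                      seed = 1L) {
  mode <- match.arg(mode)
  if (!name %in% names(.presetTable))
    stop("unknown preset '", name, "'; see aucPresets()")
  p <- .presetTable[[name]]
  solute <- soluteProperties(p$label, s = p$s, D = p$D, M = p$M,
                             buoyancy = p$buoyancy)
  cond <- p[[mode]]
  run <- if (is.null(cond)) NULL else
    runConditions(rpm = cond[["rpm"]], tRun = cond[["tRun"]],
                  nSteps = nSteps, nScans = nScans,
                  nParticles = nParticles, seed = seed)
  list(solute = solute, run = run)
}

#' @rdname aucPreset
#' @export
aucPresets <- function() names(.presetTable)
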