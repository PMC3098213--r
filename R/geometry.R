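#' Construct a sector-cell geometry
#'
#' Defaults are a standard 12 mm double-sector centerpiece: meniscus at
#' 5.80 cm, bottom at 7.20 cm, sector angle 3 degrees (0.05236 rad), and 100
#' radial slices for binning.
#'
#' @param rMeniscus meniscus radius (cm).
#' @param rBottom bottom radius (cm).
#' @param phi sector angle (rad).
#' @param height cell height (cm).
#' @param nRadial number of radial slices.
#' @return A [CellGeometry-class] object.
#' @examples
#' cellGeometry()
#' @export
cellGeometry <- function(rMeniscus = 5.80, rBottom = 7.20, phi = 0.05236,
                         height = 1.0, nRadial = 100L) {
  new("CellGeometry", rMeniscus = rMeniscus, rBottom = rBottom, phi = phi,
      height = height, nRadial = as.integer(nRadial))
}

#' @describeIn cellGeometry radial slice width
#'   `chi = (rBottom - rMeniscus) / nRadial` (cm).
#' @param geom a [CellGeometry-class].
#' @export
sliceWidth <- function(geom) (geom@rBottom - geom@rMeniscus) / geom@nRadial

#' @describeIn cellGeometry bin-center radii `r_i = rMeniscus + (i - 1/2) chi`
#'   (cm).
#' @export
binRadii <- function(geom) {
  chi <- sliceWidth(geom)
  geom@rMeniscus + (seq_len(geom@nRadial) - 0.5) * chi
}

#' Construct run conditions
#'
#' @param rpm rotor speed (revolutions per minute).
#' @param tRun total experiment time (s).
#' @param nSteps BD steps per trajectory; must be a multiple of `nScans`.
#'   50 large steps reproduce the many-small-steps algorithm within
#'   Monte-Carlo noise (the drift is integrated exactly within a step and the
#'   Brownian increment is self-similar).
#' @param nScans recorded scans, at `t_j = j * tRun / nScans`.
#' @param nParticles number of independent particles; 1e5 gives a low noise
#'   level at 100 slices.
#' @param seed global random seed.
#' @return A [RunConditions-class] object.
#' @examples
#' runConditions(rpm = 40000, tRun = 40000)
#' @export
runConditions <- function(rpm, tRun, nSteps = 50L, nScans = 50L,
                          nParticles = 1e5, seed = 1L) {
  new("RunConditions", rpm = rpm, tRun = tRun, nSteps = as.integer(nSteps),
      nScans = as.integer(nScans), nParticles = as.integer(nParticles),
      seed = as.integer(seed))
}

#' @describeIn runConditions BD time step `tRun / nSteps` (s).
#' @param run a [RunConditions-class].
#' @export
timeStep <- function(run) run@tRun / run@nSteps

#' @describeIn runConditions scan interval `tau = tRun / nScans` (s).
#' @export
scanInterval <- function(run) run@tRun / run@nScans
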