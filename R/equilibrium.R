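#' Closed-form sedimentation-equilibrium profile
#'
#' At sedimentation equilibrium the classical single-species result is
#' `c(r) = c0 exp(omega^2 M (1 - vbar rho) (r^2 - rMeniscus^2) / (2 R T))`,
#' i.e. `c/c0 = exp(sigma (r^2 - rMeniscus^2) / 2)` with sigma from
#' [reducedMassSigma()]. The profile equals 1 at the meniscus for any M.
#'
#' @param geom a [CellGeometry-class]; the profile is evaluated at its bin
#'   centers unless `radii` is given.
#' @param M molar mass (g mol^-1).
#' @param buoyancy buoyancy factor 1 - vbar*rho.
#' @param omega angular velocity (rad s^-1).
#' @param constants a [PhysicalConstants-class].
#' @param radii optional radii (cm) within the cell.
#' @return A single-scan [ConcentrationProfile-class] with provenance
#'   `"analytic"` (time slot `Inf`).
#' @examples
#' p <- equilibriumProfileAnalytic(cellGeometry(), M = 14.3e3,
#'                                 buoyancy = 0.298,
#'                                 omega = rpmToOmega(15000))
#' range(profileValues(p))
#' @export
equilibriumProfileAnalytic <- function(geom, M, buoyancy, omega,
                                       constants = physicalConstants(),
                                       radii = NULL) {
  if (is.null(radii)) radii <- binRadii(geom)
  if (any(radii < geom@rMeniscus - 1e-12 | radii > geom@rBottom + 1e-12))
    stop("radii must lie within [rMeniscus, rBottom]")
  sigma <- reducedMassSigma(M, buoyancy, omega, constants)
  vals <- matrix(exp(sigma * (radii^2 - geom@rMeniscus^2) / 2), ncol = 1)
  new("ConcentrationProfile", radii = radii, times = Inf, values = vals,
      provenance = "analytic", c0 = 1, rpm = omega * 60 / (2 * pi))
}

#' Molar mass from the linearized equilibrium fit
#'
#' Ordinary least squares of `ln c(r)` against `x = r^2 - rMeniscus^2` over
#' the interior of the cell; the slope is
#' `omega^2 M (1 - vbar rho) / (2 R T)`, so
#' `M = 2 R T slope / (omega^2 (1 - vbar rho))`. Bins within
#' `exclusion * (column length)` of either end are discarded, as are bins
#' with `c/c0` below `minConcentration` (log-domain noise); non-positive
#' concentrations are excluded, never log-transformed. The fit is
#' unweighted, and invariant to an overall scaling of the profile (the
#' scale enters the intercept only).
#'
#' @param profile a [ConcentrationProfile-class].
#' @param buoyancy buoyancy factor 1 - vbar*rho.
#' @param omega angular velocity (rad s^-1).
#' @param rMeniscus meniscus radius (cm); defaults to just below the first
#'   bin center (half a slice), matching profiles built on bin centers of a
#'   full cell.
#' @param scan scan (column) index to fit; defaults to the final scan.
#' @param exclusion fraction of the column length excluded at each end.
#' @param minConcentration lower c/c0 cutoff for inclusion.
#' @param constants a [PhysicalConstants-class].
#' @return An [EquilibriumFit-class]. Its `convergence` slot holds the
#'   maximum absolute change in c/c0 between the last two scans (`NA` for
#'   single-scan profiles), a diagnostic of equilibration.
#' @examples
#' geom <- cellGeometry()
#' p <- equilibriumProfileAnalytic(geom, 14.3e3, 0.298, rpmToOmega(15000))
#' fit <- fitEquilibriumMass(p, 0.298, rpmToOmega(15000),
#'                           rMeniscus = geom@rMeniscus)
#' molarMass(fit)  # 14300 to machine precision
#' @export
fitEquilibriumMass <- function(profile, buoyancy, omega,
                               rMeniscus = NULL,
                               scan = length(profile@times),
                               exclusion = 0.05, minConcentration = 1e-3,
                               constants = physicalConstants()) {
  r <- profile@radii
  if (is.null(rMeniscus)) {
    half <- if (length(r) > 1) diff(r[1:2]) / 2 else 0
    rMeniscus <- r[1] - half
  }
  v <- profile@values[, scan]
  span <- max(r) - min(r)
  lo <- min(r) + exclusion * span
  hi <- max(r) - exclusion * span
  keep <- r >= lo & r <= hi & v > 0 & v >= minConcentration
  if (sum(keep) < 3)
    stop("insufficient data: fewer than 3 usable bins in the fit window")
  x <- r[keep]^2 - rMeniscus^2
  y <- log(v[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  mFit <- 2 * constants@gasR * constants@temperature * slope /
    (omega^2 * buoyancy)
  conv <- NA_real_
  if (length(profile@times) >= 2) {
    nT <- length(profile@times)
    conv <- max(abs(profile@values[, nT] - profile@values[, nT - 1L]))
  }
  new("EquilibriumFit",
      mFit = unname(mFit), slope = unname(slope),
      intercept = unname(fit$coefficients[1]),
      window = c(min(r[keep]), max(r[keep])),
      nPoints = as.integer(sum(keep)),
      residualRMS = sqrt(mean(fit$residuals^2)),
      convergence = conv)
}
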