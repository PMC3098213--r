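#' Physical constants at a given temperature
#'
#' CGS values: Boltzmann constant 1.380649e-16 erg/K, Avogadro's number
#' 6.02214076e23 /mol, gas constant derived as their product
#' (8.3145e7 erg mol^-1 K^-1). The default temperature of 293.15 K (20 degC)
#' is the standard reporting temperature of sedimentation experiments.
#'
#' @param temperature absolute temperature in K.
#' @return A [PhysicalConstants-class] object.
#' @examples
#' physicalConstants()          # 20 degC
#' physicalConstants(298.15)    # 25 degC
#' @export
physicalConstants <- function(temperature = 293.15) {
  kB <- 1.380649e-16
  nA <- 6.02214076e23
  new("PhysicalConstants", kB = kB, nAvogadro = nA, gasR = kB * nA,
      temperature = temperature)
}

#' Construct solute properties
#'
#' @param name species label.
#' @param s sedimentation coefficient, in Svedberg by default
#'   (`sUnit = "svedberg"`, 1 S = 1e-13 s) or in seconds.
#' @param D diffusion coefficient (cm^2 s^-1).
#' @param M molar mass (g mol^-1).
#' @param buoyancy buoyancy factor 1 - vbar*rho (dimensionless).
#' @param sUnit unit of `s`.
#' @param constants if a [PhysicalConstants-class] is supplied, the friction
#'   coefficient is derived from `D` by the Einstein relation `f = kB T / D`
#'   and stored; otherwise the friction slot is `NA`.
#' @return A [SoluteProperties-class] object.
#' @examples
#' soluteProperties("lysozyme", s = 1.89, D = 10.8e-7, M = 14.3e3,
#'                  buoyancy = 0.298)
#' @export
soluteProperties <- function(name = "", s, D, M, buoyancy,
                             sUnit = c("svedberg", "seconds"),
                             constants = NULL) {
  sUnit <- match.arg(sUnit)
  sSec <- if (sUnit == "svedberg") s * 1e-13 else s
  friction <- NA_real_
  if (!is.null(constants)) friction <- frictionFromD(D, constants)
  new("SoluteProperties", name = name, s = sSec, D = D, M = M,
      buoyancy = buoyancy, friction = friction)
}

#' Rotor speed to angular velocity
#'
#' @param rpm rotor speed in revolutions per minute; vectorized.
#' @return Angular velocity omega in rad s^-1 (`rpm * 2 pi / 60`).
#' @examples
#' rpmToOmega(40000)  # 4188.79 rad/s
#' @export
rpmToOmega <- function(rpm) {
  if (any(!is.finite(rpm)) || any(rpm < 0))
    stop("rpm must be finite and non-negative")
  rpm * 2 * pi / 60
}

#' Molar mass from the Svedberg relation
#'
#' `s / D = M (1 - vbar rho) / (R T)`, solved for the molar mass:
#' `M = s R T / (D (1 - vbar rho))`.
#'
#' @param s sedimentation coefficient in seconds (not Svedberg).
#' @param D diffusion coefficient (cm^2 s^-1), positive.
#' @param buoyancy buoyancy factor 1 - vbar*rho, positive.
#' @param constants a [PhysicalConstants-class].
#' @return Molar mass in g mol^-1.
#' @examples
#' svedbergMass(1.89e-13, 10.8e-7, 0.298)  # ~14.3e3 g/mol
#' @export
svedbergMass <- function(s, D, buoyancy, constants = physicalConstants()) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(buoyancy <= 0)) stop("buoyancy factor must be positive")
  s * constants@gasR * constants@temperature / (D * buoyancy)
}

#' Friction coefficient from the Einstein relation
#'
#' `D = kB T / f`, solved for the friction coefficient `f = kB T / D`.
#'
#' @inheritParams svedbergMass
#' @return Friction coefficient in g s^-1.
#' @export
frictionFromD <- function(D, constants = physicalConstants()) {
  if (any(D <= 0)) stop("D must be positive")
  constants@kB * constants@temperature / D
}

#' Deterministic sedimentation velocity
#'
#' The radial drift velocity `v = s omega^2 r` of a particle at radius `r`
#' under centrifugal acceleration `omega^2 r`.
#'
#' @param s sedimentation coefficient (seconds).
#' @param omega angular velocity (rad s^-1).
#' @param r radius (cm), positive.
#' @return Radial velocity in cm s^-1.
#' @export
sedimentationVelocity <- function(s, omega, r) {
  if (any(r <= 0)) stop("r must be positive")
  s * omega^2 * r
}

#' Reduced molar mass
#'
#' `sigma = omega^2 M (1 - vbar rho) / (R T)` (cm^-2), the decay constant of
#' the sedimentation-equilibrium exponential: at equilibrium
#' `c(r)/c0 = exp(sigma (r^2 - rMeniscus^2) / 2)`. By the Svedberg relation
#' `sigma = omega^2 s / D`.
#'
#' @param M molar mass (g mol^-1).
#' @param buoyancy buoyancy factor 1 - vbar*rho.
#' @param omega angular velocity (rad s^-1).
#' @param constants a [PhysicalConstants-class].
#' @return sigma in cm^-2.
#' @export
reducedMassSigma <- function(M, buoyancy, omega,
                             constants = physicalConstants()) {
  omega^2 * M * buoyancy / (constants@gasR * constants@temperature)
}
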