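#' Per-particle random streams
#'
#' Every particle `k` owns a counter-based substream derived from the global
#' seed and `k` alone, so the variates it draws never depend on execution
#' order or on how particles are partitioned over workers. A trajectory
#' consumes exactly one uniform (initial position) followed by two uniforms
#' per BD step (a Box-Muller pair yielding the standard-normal Brownian
#' increment).
#'
#' @param seed global random seed (integer).
#' @param particle particle index (integer, 0-based).
#' @param n number of variates.
#' @param skip number of uniforms to discard before the first normal
#'   (`skip = 1` skips the initial-position draw).
#' @return `streamUniforms()`: `n` uniforms on (0, 1); `streamNormals()`:
#'   `n` standard-normal variates.
#' @examples
#' streamUniforms(1, 0, 3)
#' identical(streamNormals(1, 7, 5), streamNormals(1, 7, 5))
#' @export
streamUniforms <- function(seed, particle, n) {
  cpp_stream_uniforms(as.integer(seed), as.integer(particle), as.integer(n))
}

#' @rdname streamUniforms
#' @export
streamNormals <- function(seed, particle, n, skip = 0L) {
  cpp_stream_normals(as.integer(seed), as.integer(particle), as.integer(n),
                     as.integer(skip))
}

#' Initial radial position by inverse-transform sampling
#'
#' In a uniformly loaded sector cell the number of particles in a slice at
#' radius r is proportional to r, so the initial position has density
#' `p(r) = 2 r / (rBottom^2 - rMeniscus^2)` and CDF
#' `F(r) = (r^2 - rMeniscus^2) / (rBottom^2 - rMeniscus^2)`. Inverting F at a
#' uniform variate u gives the radius `sqrt(u (rBottom^2 - rMeniscus^2) +
#' rMeniscus^2)`.
#'
#' @param u uniform variate(s) in \[0, 1\].
#' @param geom a [CellGeometry-class].
#' @return Radius (cm) in \[rMeniscus, rBottom\]; vectorized over `u`.
#' @examples
#' sampleInitialPosition(c(0, 0.5, 1), cellGeometry())
#' @export
sampleInitialPosition <- function(u, geom) {
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  sqrt(u * (geom@rBottom^2 - geom@rMeniscus^2) + geom@rMeniscus^2)
}

#' Deterministic drift over one step
#'
#' The sedimentation drift `v = s omega^2 r` integrates exactly to
#' exponential growth, `r(t + dt) = r(t) exp(s omega^2 dt)`, so the drift
#' displacement over a step of any length is
#' `r(t) * (exp(s omega^2 dt) - 1)`, evaluated at the start-of-step position.
#'
#' @param r start-of-step radius (cm), positive; vectorized.
#' @param s sedimentation coefficient (seconds).
#' @param omega angular velocity (rad s^-1).
#' @param dt step length (s), non-negative.
#' @return Drift displacement (cm), non-negative for `s >= 0`.
#' @export
driftDisplacement <- function(r, s, omega, dt) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(dt < 0)) stop("dt must be non-negative")
  r * expm1(s * omega^2 * dt)
}

#' Brownian displacement over one step
#'
#' Zero-mean displacement with variance `2 D dt`. Thanks to the
#' self-similarity of Brownian motion this law holds for steps of any
#' length, which is what makes the large-step algorithm exact in the cell
#' interior. The increment distribution is normal (the free-space
#' propagator).
#'
#' @param D diffusion coefficient (cm^2 s^-1), non-negative.
#' @param dt step length (s), non-negative.
#' @param z standard-normal variate(s), e.g. from [streamNormals()].
#' @return Displacement(s) in cm, `sqrt(2 D dt) * z`.
#' @export
brownianDisplacement <- function(D, dt, z) {
  if (any(D < 0)) stop("D must be non-negative")
  if (any(dt < 0)) stop("dt must be non-negative")
  sqrt(2 * D * dt) * z
}

#' End-of-step boundary rules
#'
#' A particle crossing the meniscus is stopped there (a radius below
#' `rMeniscus` maps to `rMeniscus`); a particle crossing the bottom bounces
#' (a radius above `rBottom` maps to `2 rBottom - r`). The rules iterate until
#' the position is inside the cell, which protects against Brownian steps
#' larger than the column.
#'
#' @param r radius/radii (cm), finite.
#' @param geom a [CellGeometry-class].
#' @return Radii in \[rMeniscus, rBottom\].
#' @export
applyBoundaries <- function(r, geom) {
  if (any(!is.finite(r))) stop("r must be finite")
  rm <- geom@rMeniscus
  rb <- geom@rBottom
  repeat {
    out <- r > rb
    if (any(out)) r[out] <- 2 * rb - r[out]
    under <- r < rm
    if (any(under)) r[under] <- rm
    if (!any(r > rb)) break
  }
  r
}

#' Advance one particle position by one BD step
#'
#' Position update (start radius plus drift plus Brownian displacement) followed
#' by [applyBoundaries()]; the drift uses the start-of-step position.
#'
#' @inheritParams applyBoundaries
#' @param r start-of-step radius (cm).
#' @param solute a [SoluteProperties-class].
#' @param omega angular velocity (rad s^-1).
#' @param dt step length (s).
#' @param z standard-normal variate(s).
#' @return End-of-step radius (cm) inside the cell.
#' @export
stepParticle <- function(r, solute, omega, dt, z, geom) {
  applyBoundaries(
    r + driftDisplacement(r, solute@s, omega, dt) +
      brownianDisplacement(solute@D, dt, z),
    geom)
}

# Pure-R replica of the compiled trajectory loop, consuming the same
# per-particle stream. Used as the cross-check route in tests.
bdTrajectoryReference <- function(particle, solute, geom, run) {
  omega <- rpmToOmega(run@rpm)
  dt <- timeStep(run)
  stepsPerScan <- run@nSteps %/% run@nScans
  u <- streamUniforms(run@seed, particle, 1L + 2L * run@nSteps)
  r <- sampleInitialPosition(u[1], geom)
  rec <- numeric(run@nScans + 1L)
  rec[1] <- r
  j <- 2L
  for (step in seq_len(run@nSteps)) {
    u1 <- u[2L * step]
    u2 <- u[2L * step + 1L]
    z <- sqrt(-2 * log(u1)) * cos(2 * pi * u2)
    r <- stepParticle(r, solute, omega, dt, z, geom)
    if (step %% stepsPerScan == 0L) {
      rec[j] <- r
      j <- j + 1L
    }
  }
  rec
}

#' Simulate the particle-count matrix of an AUC run
#'
#' Runs `nParticles` independent Brownian-dynamics trajectories through the
#' sector cell and counts, at each scan time, the particles per radial
#' slice. With `workers > 1` the particles are partitioned over forked
#' processes; the per-particle streams make the result bitwise identical for
#' any partitioning.
#'
#' @param solute a [SoluteProperties-class].
#' @param geom a [CellGeometry-class].
#' @param run a [RunConditions-class].
#' @param workers worker processes (requires the parallel package for
#'   `workers > 1`; falls back to serial where forking is unavailable).
#' @return A [CountMatrix-class].
#' @examples
#' cm <- simulateCounts(
#'   soluteProperties("lysozyme", 1.89, 10.8e-7, 14.3e3, 0.298),
#'   cellGeometry(),
#'   runConditions(rpm = 40000, tRun = 40000, nParticles = 1000))
#' all(colSums(counts(cm)) == 1000)
#' @export
simulateCounts <- function(solute, geom, run, workers = 1L) {
  omega <- rpmToOmega(run@rpm)
  stepsPerScan <- run@nSteps %/% run@nScans
  args <- function(n, off) {
    cpp_bd_counts(as.integer(n), as.integer(off), run@seed,
                  solute@s, solute@D, omega,
                  geom@rMeniscus, geom@rBottom, geom@nRadial,
                  timeStep(run), run@nSteps, as.integer(stepsPerScan))
  }
  workers <- as.integer(workers)
  if (workers > 1L && requireNamespace("parallel", quietly = TRUE) &&
      .Platform$OS.type == "unix") {
    offsets <- floor(seq(0L, run@nParticles, length.out = workers + 1L))
    sizes <- diff(offsets)
    keep <- sizes > 0
    parts <- parallel::mcmapply(args, sizes[keep], offsets[-length(offsets)][keep],
                                SIMPLIFY = FALSE, mc.cores = workers)
    m <- Reduce(`+`, parts)
  } else {
    m <- args(run@nParticles, 0L)
  }
  new("CountMatrix", counts = m, geometry = geom,
      scanTimes = scanTimes(run), nParticles = run@nParticles)
}

#' Simulate and record particle trajectories at scan times
#'
#' @inheritParams simulateCounts
#' @param particles 0-based particle indices to record; defaults to all
#'   `nParticles`.
#' @return Numeric matrix with `nScans + 1` rows (initial position, then one
#'   row per scan time) and one column per particle; identical to the
#'   positions [simulateCounts()] bins.
#' @export
simulateTrajectories <- function(solute, geom, run, particles = NULL) {
  if (is.null(particles)) particles <- seq_len(run@nParticles) - 1L
  omega <- rpmToOmega(run@rpm)
  stepsPerScan <- run@nSteps %/% run@nScans
  rec <- cpp_bd_trajectories(as.integer(particles), run@seed,
                             solute@s, solute@D, omega,
                             geom@rMeniscus, geom@rBottom,
                             timeStep(run), run@nSteps,
                             as.integer(stepsPerScan))
  dimnames(rec) <- NULL
  rec
}

#' Bin recorded positions into a count matrix
#'
#' The slice index of a radius r is `floor((r - rMeniscus) / chi) + 1`,
#' capped at `nRadial` so that the bottom radius falls in the last slice.
#'
#' @param records matrix of radii as returned by [simulateTrajectories()]
#'   (scan rows, particle columns); the initial row, if present at time 0,
#'   must be dropped by the caller before counting scans only.
#' @param geom a [CellGeometry-class].
#' @param times scan times (s), one per row of `records`.
#' @return A [CountMatrix-class].
#' @export
accumulateCounts <- function(records, geom, times) {
  if (nrow(records) != length(times))
    stop("records must have one row per scan time")
  rm <- geom@rMeniscus
  rb <- geom@rBottom
  if (any(records < rm | records > rb))
    stop("all radii must lie inside [rMeniscus, rBottom]")
  chi <- sliceWidth(geom)
  idx <- pmin(floor((records - rm) / chi), geom@nRadial - 1L) + 1L
  m <- vapply(seq_len(nrow(records)),
              function(j) tabulate(idx[j, ], nbins = geom@nRadial),
              integer(geom@nRadial))
  new("CountMatrix", counts = m, geometry = geom, scanTimes = times,
      nParticles = ncol(records))
}
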