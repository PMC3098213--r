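test_that("initial positions invert the sector-loading CDF", {
  geom <- stdGeom()
  expect_equal(sampleInitialPosition(0, geom), 5.80)
  expect_equal(sampleInitialPosition(1, geom), 7.20)
  # sqrt(0.5 * (7.2^2 - 5.8^2) + 5.8^2), by hand
  expect_equal(sampleInitialPosition(0.5, geom), 6.537584, tolerance = 1e-6)
  expect_error(sampleInitialPosition(1.1, geom), "\\[0, 1\\]")
})

test_that("initial ensemble matches F(r) = (r^2-rm^2)/(rb^2-rm^2)", {
  geom <- stdGeom()
  sol <- aucPreset("lysozyme")$solute
  run <- runConditions(15000, 1000, nSteps = 1L, nScans = 1L,
                       nParticles = 1e5, seed = 42L)
  r0 <- simulateTrajectories(sol, geom, run)[1, ]
  Fr <- function(r) (r^2 - 5.8^2) / (7.2^2 - 5.8^2)
  ks <- max(abs(seq_along(r0) / length(r0) - Fr(sort(r0))))
  expect_lt(ks, 1.628 / sqrt(length(r0)))  # 1% KS critical value
})

test_that("drift integrates the exponential law exactly", {
  expect_equal(driftDisplacement(6.5, 0, 5000, 100), 0)
  # T7 DNA nearly traverses the cell over its full velocity run
  om <- rpmToOmega(10000)
  d <- driftDisplacement(5.80, 31.8e-13, om, 60000)
  expect_equal(d, 1.34986, tolerance = 2e-5)
  expect_equal(5.80 + d, 7.1499, tolerance = 1e-4)
  # semigroup: two half steps compose to one full step
  r1 <- 6.1 + driftDisplacement(6.1, 31.8e-13, om, 30000)
  r2 <- r1 + driftDisplacement(r1, 31.8e-13, om, 30000)
  expect_equal(r2, 6.1 + driftDisplacement(6.1, 31.8e-13, om, 60000),
               tolerance = 1e-12)
})

test_that("Brownian increments have zero mean and variance 2 D dt", {
  D <- 10.8e-7
  dt <- 800
  z <- streamNormals(7L, 0L, 1e6)
  x <- brownianDisplacement(D, dt, z)
  expect_equal(var(x), 2 * D * dt, tolerance = 0.01)
  expect_lt(abs(mean(x)), 3 * sqrt(2 * D * dt / 1e6))
  expect_identical(brownianDisplacement(0, dt, z), numeric(1e6))
})

test_that("boundary rules clamp at the meniscus and bounce at the bottom", {
  geom <- stdGeom()
  expect_equal(applyBoundaries(6.50, geom), 6.50)
  expect_equal(applyBoundaries(5.75, geom), 5.80)
  expect_equal(applyBoundaries(7.25, geom), 7.15)  # 2*7.2 - 7.25
  # a step far beyond the bottom bounces, then clamps at the meniscus
  expect_equal(applyBoundaries(9.0, geom), 5.80)
  expect_true(all(applyBoundaries(runif(100, 0, 20), geom) >= 5.8))
  expect_error(applyBoundaries(NaN, geom), "finite")
})

test_that("D = 0 trajectories follow the deterministic exponential", {
  geom <- stdGeom()
  sol <- soluteProperties("dna-like", s = 31.8, D = 0, M = 26e6,
                          buoyancy = 0.45)
  run <- runConditions(10000, 20000, nSteps = 40L, nScans = 10L,
                       nParticles = 5L, seed = 3L)
  rec <- simulateTrajectories(sol, geom, run)
  om <- rpmToOmega(10000)
  growth <- exp(sol@s * om^2 * c(0, scanTimes(run)))
  free <- rec[1, ] * max(growth) < 7.2  # particles that never hit the bottom
  expect_gt(sum(free), 0)
  for (k in which(free))
    expect_equal(rec[, k], rec[1, k] * growth, tolerance = 1e-12)
  # a particle that reaches the bottom stays within one bounce of it
  stepGrowth <- exp(sol@s * om^2 * 20000 / 40)
  for (k in which(!free)) {
    hit <- rec[, k] * stepGrowth > 7.2
    expect_true(all(rec[hit, k] >= 7.2 / stepGrowth & rec[hit, k] <= 7.2))
  }
  # with s = 0 as well, positions never move
  sol0 <- soluteProperties("inert", s = 0, D = 0, M = 1, buoyancy = 0.5)
  rec0 <- simulateTrajectories(sol0, geom, run)
  expect_true(all(rec0 == rec0[rep(1, nrow(rec0)), ]))
})

test_that("per-particle streams are reproducible and order-independent", {
  expect_identical(streamUniforms(1L, 5L, 10L), streamUniforms(1L, 5L, 10L))
  expect_false(any(streamUniforms(1L, 5L, 10L) ==
                     streamUniforms(1L, 6L, 10L)))
  expect_false(any(streamUniforms(1L, 5L, 10L) ==
                     streamUniforms(2L, 5L, 10L)))
  u <- streamUniforms(9L, 3L, 1000L)
  expect_true(all(u > 0 & u < 1))
})

test_that("count matrices are bitwise invariant to particle partitioning", {
  geom <- stdGeom()
  sol <- aucPreset("lysozyme")$solute
  run <- smallRun(40000, 40000, nParticles = 3000)
  whole <- simulateCounts(sol, geom, run)
  # simulate the same particles in unequal chunks via the workers path
  split2 <- simulateCounts(sol, geom, run, workers = 2L)
  split7 <- simulateCounts(sol, geom, run, workers = 7L)
  expect_identical(counts(whole), counts(split2))
  expect_identical(counts(whole), counts(split7))
  # and repeat runs are bitwise identical
  expect_identical(counts(whole), counts(simulateCounts(sol, geom, run)))
})

test_that("compiled engine matches the pure-R replica step for step", {
  geom <- stdGeom()
  sol <- aucPreset("cyclodextrin")$solute
  run <- smallRun(55000, 40000, nParticles = 20, nScans = 10L)
  rec <- simulateTrajectories(sol, geom, run)
  for (k in c(0L, 7L, 19L)) {
    refk <- aucBD:::bdTrajectoryReference(k, sol, geom, run)
    expect_equal(rec[, k + 1L], unname(refk), tolerance = 1e-12)
  }
})

test_that("counting conserves particles and respects edge conventions", {
  geom <- stdGeom(nRadial = 10L)
  # one particle pinned at each edge
  rec <- matrix(c(5.8, 7.2), nrow = 2, ncol = 2, byrow = TRUE)
  cm <- accumulateCounts(rec, geom, times = c(10, 20))
  expect_equal(counts(cm)[1, ], c(1L, 1L))
  expect_equal(counts(cm)[10, ], c(1L, 1L))
  expect_error(accumulateCounts(matrix(7.3, 1, 1), geom, 10), "inside")

  # binning the recorded trajectories reproduces the engine's own counts
  sol <- aucPreset("lysozyme")$solute
  run <- smallRun(40000, 40000, nParticles = 2000)
  geom100 <- stdGeom()
  rec <- simulateTrajectories(sol, geom100, run)
  cm2 <- accumulateCounts(rec[-1, , drop = FALSE], geom100, scanTimes(run))
  expect_identical(counts(cm2), counts(simulateCounts(sol, geom100, run)))
  expect_true(all(colSums(counts(cm2)) == 2000L))
})
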