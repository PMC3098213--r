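test_that("uniform loading maps to c/c0 = 1 in every slice", {
  geom <- stdGeom(nRadial = 20L)
  ri <- binRadii(geom)
  chi <- sliceWidth(geom)
  span2 <- 7.2^2 - 5.8^2
  nPart <- 1e5L
  # expected (non-integral) slice occupancies of the uniform state
  m <- matrix(nPart * 2 * ri * chi / span2, ncol = 2, nrow = 20)
  cm <- new("CountMatrix", counts = m, geometry = geom,
            scanTimes = c(0, 1), nParticles = nPart)
  prof <- countsToConcentration(cm)
  expect_equal(unname(profileValues(prof)),
               matrix(1, 20, 2), tolerance = 1e-12)
  expect_equal(unname(massBalance(prof)), c(1, 1), tolerance = 1e-12)
})

test_that("concentration conversion implements the radial-dilution formula", {
  geom <- stdGeom()  # chi = 0.014
  m <- matrix(0L, 100, 1)
  m[51, 1] <- 1000L
  m[1, 1] <- 99000L  # park the rest in the first bin to conserve particles
  cm <- new("CountMatrix", counts = m, geometry = geom, scanTimes = 5,
            nParticles = 1e5L)
  prof <- countsToConcentration(cm)
  r51 <- 5.8 + 50.5 * 0.014
  # (rb^2 - rm^2)/(2 chi) * (n/Npart)/r_i, by hand
  expect_equal(profileValues(prof)[51, 1], 650 * 0.01 / r51,
               tolerance = 1e-12)
  expect_equal(profileValues(prof)[60, 1], 0)
  # linear in counts
  cm2 <- cm
  cm2@counts <- m * 3L
  cm2@nParticles <- 3e5L
  expect_equal(profileValues(countsToConcentration(cm2)),
               profileValues(prof), tolerance = 1e-12)
})

test_that("BD-derived scans balance mass exactly at every scan", {
  geom <- stdGeom()
  sol <- aucPreset("lysozyme")$solute
  cm <- simulateCounts(sol, geom, smallRun(40000, 40000, nParticles = 5000))
  prof <- countsToConcentration(cm)
  expect_equal(unname(massBalance(prof)), rep(1, 10), tolerance = 1e-12)
})

test_that("profile distance is an RMS with terminal exclusion", {
  geom <- stdGeom()
  sol <- aucPreset("lysozyme")$solute
  prof <- countsToConcentration(
    simulateCounts(sol, geom, smallRun(40000, 40000)))
  expect_equal(profileDistance(prof, prof), 0)
  shifted <- prof
  shifted@values <- prof@values + 0.01
  expect_equal(profileDistance(prof, shifted), 0.01, tolerance = 1e-12)
  expect_equal(unname(profileDistance(prof, shifted, perScan = TRUE)),
               rep(0.01, 10), tolerance = 1e-12)
  other <- prof
  other@times <- prof@times + 1
  expect_error(profileDistance(prof, other), "scan times")
})

test_that("velocity-mode plateau obeys the square dilution law", {
  # T7 DNA: diffusion negligible, plateau c_p/c0 = exp(-2 s w^2 t)
  geom <- stdGeom()
  pr <- aucPreset("dna_t7", "velocity")
  om <- rpmToOmega(pr$run@rpm)
  s <- pr$solute@s
  profs <- lapply(c(11L, 23L), function(sd) {
    run <- pr$run
    run@seed <- sd
    countsToConcentration(simulateCounts(pr$solute, geom, run))
  })
  for (j in c(10L, 25L)) {
    t <- scanTimes(pr$run)[j]
    rBoundary <- 5.8 * exp(s * om^2 * t)
    keep <- radii(profs[[1]]) > rBoundary + 0.15 & radii(profs[[1]]) < 7.0
    expect_gt(sum(keep), 20)
    p1 <- profs[[1]]@values[keep, j]
    p2 <- profs[[2]]@values[keep, j]
    # noise of a single-run plateau mean, estimated from the seed pair
    noiseMean <- stats::sd(p1 - p2) / sqrt(2) / sqrt(sum(keep))
    expect_lt(abs(mean(p1) - exp(-2 * s * om^2 * t)), 3 * noiseMean)
  }
})

test_that("profile writers and readers round-trip exactly", {
  geom <- stdGeom(nRadial = 15L)
  sol <- aucPreset("cyclodextrin")$solute
  run <- smallRun(55000, 40000, nParticles = 500, nScans = 4L,
                  nSteps = 8L)
  prof <- countsToConcentration(simulateCounts(sol, geom, run))
  prof@rpm <- 55000

  long <- tempfile(fileext = ".csv")
  writeProfile(prof, long)
  back <- readProfile(long)
  expect_identical(profileValues(back), unname(profileValues(prof)))
  expect_identical(radii(back), radii(prof))
  expect_identical(scanTimes(back), scanTimes(prof))

  dir <- tempfile()
  dir.create(dir)
  files <- writeScans(prof, dir)
  expect_length(files, 4L)
  expect_match(readLines(files[2], n = 1), "^# t= .* s rpm= 55000")
  back2 <- readProfile(files)
  expect_identical(profileValues(back2), unname(profileValues(prof)))
  expect_identical(back2@rpm, 55000)
})

test_that("trajectory export writes one row per particle and time", {
  geom <- stdGeom()
  sol <- aucPreset("lysozyme")$solute
  run <- smallRun(40000, 40000, nParticles = 3, nScans = 5L, nSteps = 10L)
  rec <- simulateTrajectories(sol, geom, run)
  f <- tempfile(fileext = ".csv")
  writeTrajectories(rec, c(0, scanTimes(run)), 0:2, f)
  d <- utils::read.csv(f)
  expect_equal(nrow(d), 18L)  # (5 scans + initial) x 3 particles
  expect_equal(sort(unique(d$particle)), 0:2)
  expect_equal(d$r_cm[d$particle == 1 & d$t_s == 0], rec[1, 2])
})
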