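# Shared fixtures: the standard cell, and a reduced-size run for fast tests.
stdGeom <- function(nRadial = 100L) cellGeometry(nRadial = nRadial)

smallRun <- function(rpm, tRun, nParticles = 2000, nSteps = 50L,
                     nScans = 10L, seed = 1L) {
  runConditions(rpm = rpm, tRun = tRun, nSteps = nSteps, nScans = nScans,
                nParticles = nParticles, seed = seed)
}

# RMS distance between two independent-seed BD runs: the Monte-Carlo noise
# floor used to scale agreement thresholds.
noiseFloor <- function(solute, geom, run, seeds = c(101L, 202L),
                       exclusion = 0.05) {
  ps <- lapply(seeds, function(sd) {
    r <- run
    r@seed <- sd
    countsToConcentration(simulateCounts(solute, geom, r))
  })
  profileDistance(ps[[1]], ps[[2]], exclusion)
}
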