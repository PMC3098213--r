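test_that("presets carry the published parameters", {
  expect_setequal(aucPresets(),
                  c("cyclodextrin", "lysozyme", "peo", "dna_t7"))
  p <- aucPreset("lysozyme")
  expect_equal(p$solute@s, 1.89e-13)
  expect_equal(p$solute@D, 10.8e-7)
  expect_equal(p$solute@M, 14.3e3)
  expect_equal(p$solute@buoyancy, 0.298)
  expect_equal(p$run@rpm, 40000)
  expect_equal(p$run@tRun, 40000)
  t7 <- aucPreset("dna_t7", "velocity")
  expect_equal(t7$run@rpm, 10000)
  expect_equal(t7$run@tRun, 60000)
  expect_null(aucPreset("dna_t7", "equilibrium")$run)
  eq <- aucPreset("peo", "equilibrium")
  expect_equal(eq$run@rpm, 5000)
  expect_equal(eq$run@tRun, 5e5)
  expect_error(aucPreset("unobtainium"), "unknown preset")
})

test_that("run specs resolve presets, defaults and overrides", {
  spec <- runSpec(mode = "equilibrium", preset = "lysozyme")
  expect_equal(spec@run@rpm, 15000)
  expect_equal(spec@run@tRun, 5e5)
  expect_equal(spec@run@nParticles, 100000L)
  expect_equal(spec@geometry@nRadial, 100L)
  expect_equal(spec@geometry@rMeniscus, 5.80)
  expect_equal(spec@temperature, 293.15)
  # explicit values win over the preset
  spec2 <- runSpec(mode = "velocity", preset = "lysozyme", rpm = 20000,
                   n_part = 1000)
  expect_equal(spec2@run@rpm, 20000)
  expect_equal(spec2@run@nParticles, 1000L)
})

test_that("configuration errors name the offending fields", {
  expect_error(runSpec(mode = "sideways"), class = "aucConfigError")
  err <- tryCatch(runSpec(mode = "velocity"), error = identity)
  expect_s3_class(err, "aucConfigError")
  expect_match(conditionMessage(err), "s_svedberg")
  expect_match(conditionMessage(err), "rpm")
  expect_error(runSpec(mode = "velocity", preset = "dna_t7",
                       t_run_s = 100, n_steps = 7, n_scans = 3),
               class = "aucConfigError")
})

test_that("flat config files parse with override precedence", {
  cfg <- tempfile()
  writeLines(c("# a comment", "mode = equilibrium", "preset = peo",
               "n_part = 500", "seed = 9"), cfg)
  spec <- readRunSpec(cfg)
  expect_equal(spec@mode, "equilibrium")
  expect_equal(spec@run@nParticles, 500L)
  expect_equal(spec@run@seed, 9L)
  spec2 <- readRunSpec(cfg, overrides = list(seed = 11))
  expect_equal(spec2@run@seed, 11L)
  writeLines(c("mode = velocity", "frobnicate = 1"), cfg)
  expect_error(readRunSpec(cfg), "frobnicate")
  writeLines(c("mode = velocity", "preset = peo", "n_part = lots"), cfg)
  expect_error(readRunSpec(cfg), "numeric")
  expect_error(readRunSpec(tempfile()), "not found")
})

test_that("runAUC writes reproducible outputs and a summary", {
  out1 <- tempfile()
  spec <- runSpec(mode = "equilibrium", preset = "cyclodextrin",
                  n_part = 2000, n_r = 30, n_steps = 20, n_scans = 10,
                  seed = 4, out_dir = out1)
  res <- runAUC(spec)
  expect_true(file.exists(file.path(out1, "profile.csv")))
  expect_true(file.exists(file.path(out1, "equilibrium_fit.txt")))
  expect_true(file.exists(file.path(out1, "summary.txt")))
  expect_s4_class(res$fit, "EquilibriumFit")
  summ <- readLines(file.path(out1, "summary.txt"))
  expect_true(any(grepl("^seed = 4$", summ)))
  expect_true(any(grepl("^mode = equilibrium$", summ)))

  # identical spec + seed -> bitwise identical profiles
  out2 <- tempfile()
  spec2 <- spec
  spec2@outDir <- out2
  runAUC(spec2)
  expect_identical(readLines(file.path(out2, "profile.csv")),
                   readLines(file.path(out1, "profile.csv")))
  # a different seed changes them
  out3 <- tempfile()
  spec3 <- runSpec(mode = "equilibrium", preset = "cyclodextrin",
                   n_part = 2000, n_r = 30, n_steps = 20, n_scans = 10,
                   seed = 5, out_dir = out3)
  runAUC(spec3)
  expect_false(identical(readLines(file.path(out3, "profile.csv")),
                         readLines(file.path(out1, "profile.csv"))))
})

test_that("runAUC can attach the Lamm comparison", {
  out <- tempfile()
  spec <- runSpec(mode = "velocity", preset = "cyclodextrin",
                  n_part = 2000, n_r = 50, n_steps = 10, n_scans = 5,
                  out_dir = out)
  res <- runAUC(spec, compareLamm = TRUE)
  expect_true(file.exists(file.path(out, "lamm_rms.csv")))
  expect_true(is.numeric(res$lamm$pooled))
  expect_length(res$lamm$perScan, 5L)
})
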