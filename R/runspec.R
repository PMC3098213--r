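# Configuration keys accepted in flat key = value files and as overrides.
.configKeys <- c("mode", "preset", "s_svedberg", "d_cm2_per_s",
                 "mass_g_per_mol", "buoyancy", "rpm", "t_run_s", "n_part",
                 "n_r", "n_steps", "n_scans", "r_m_cm", "r_b_cm", "phi_rad",
                 "temperature_k", "seed", "exclusion_fraction", "workers",
                 "out_dir")

.configError <- function(...) {
  stop(errorCondition(paste0(...), class = c("aucConfigError", "error")))
}

#' Build a validated run specification
#'
#' Resolves a preset and/or explicit solute parameters, geometry, run
#' conditions and analysis options into a [RunSpec-class]. Explicit
#' arguments override preset values; anything left unset falls back to the
#' documented defaults (1e5 particles, 100 slices, 50 steps, 50 scans,
#' 293.15 K, cell \[5.80, 7.20\] cm, sector angle 0.05236 rad, 5% terminal
#' exclusion).
#'
#' @param mode `"velocity"` or `"equilibrium"`.
#' @param preset optional preset name, see [aucPresets()].
#' @param s_svedberg,d_cm2_per_s,mass_g_per_mol,buoyancy solute parameters
#'   (s in Svedberg).
#' @param rpm,t_run_s rotor speed and run duration.
#' @param n_part,n_r,n_steps,n_scans discretization.
#' @param r_m_cm,r_b_cm,phi_rad cell geometry.
#' @param temperature_k absolute temperature.
#' @param seed global random seed.
#' @param exclusion_fraction terminal exclusion for analyses.
#' @param workers worker processes.
#' @param out_dir output directory for [runAUC()].
#' @return A [RunSpec-class].
#' @examples
#' spec <- runSpec(mode = "equilibrium", preset = "lysozyme")
#' spec
#' @export
runSpec <- function(mode = "velocity", preset = NULL,
                    s_svedberg = NULL, d_cm2_per_s = NULL,
                    mass_g_per_mol = NULL, buoyancy = NULL,
                    rpm = NULL, t_run_s = NULL,
                    n_part = 1e5, n_r = 100L, n_steps = 50L, n_scans = 50L,
                    r_m_cm = 5.80, r_b_cm = 7.20, phi_rad = 0.05236,
                    temperature_k = 293.15, seed = 1L,
                    exclusion_fraction = 0.05, workers = 1L,
                    out_dir = ".") {
  if (!mode %in% c("velocity", "equilibrium"))
    .configError("mode must be 'velocity' or 'equilibrium', got '", mode, "'")
  presetName <- ""
  if (!is.null(preset)) {
    if (!preset %in% aucPresets())
      .configError("unknown preset '", preset, "'")
    presetName <- preset
    p <- aucPreset(preset, mode)
    if (is.null(s_svedberg)) s_svedberg <- p$solute@s * 1e13
    if (is.null(d_cm2_per_s)) d_cm2_per_s <- p$solute@D
    if (is.null(mass_g_per_mol)) mass_g_per_mol <- p$solute@M
    if (is.null(buoyancy)) buoyancy <- p$solute@buoyancy
    if (is.null(p$run) && (is.null(rpm) || is.null(t_run_s)))
      .configError("preset '", preset, "' has no ", mode,
                   " conditions; give rpm and t_run_s explicitly")
    if (!is.null(p$run)) {
      if (is.null(rpm)) rpm <- p$run@rpm
      if (is.null(t_run_s)) t_run_s <- p$run@tRun
    }
  }
  missing <- c("s_svedberg", "d_cm2_per_s", "mass_g_per_mol", "buoyancy",
               "rpm", "t_run_s")[vapply(
    list(s_svedberg, d_cm2_per_s, mass_g_per_mol, buoyancy, rpm, t_run_s),
    is.null, logical(1))]
  if (length(missing))
    .configError("required fields missing: ",
                 paste(missing, collapse = ", "))
  solute <- tryCatch(
    soluteProperties(if (nzchar(presetName)) presetName else "solute",
                     s = s_svedberg, D = d_cm2_per_s, M = mass_g_per_mol,
                     buoyancy = buoyancy),
    error = function(e) .configError("invalid solute: ", conditionMessage(e)))
  geom <- tryCatch(
    cellGeometry(r_m_cm, r_b_cm, phi_rad, nRadial = n_r),
    error = function(e) .configError("invalid geometry: ",
                                     conditionMessage(e)))
  run <- tryCatch(
    runConditions(rpm, t_run_s, n_steps, n_scans, n_part, seed),
    error = function(e) .configError("invalid run conditions: ",
                                     conditionMessage(e)))
  spec <- tryCatch(
    new("RunSpec", mode = mode, solute = solute, geometry = geom, run = run,
        temperature = temperature_k, exclusion = exclusion_fraction,
        workers = as.integer(workers), outDir = out_dir,
        preset = presetName),
    error = function(e) .configError(conditionMessage(e)))
  spec
}

#' Read a run specification from a flat configuration file
#'
#' The file holds one `key = value` pair per line (`#` comments and blank
#' lines ignored); every key has an identically named argument of
#' [runSpec()], and `overrides` (e.g. parsed command-line flags) take
#' precedence over file values. Unknown keys raise a configuration error
#' naming the key.
#'
#' @param path configuration file.
#' @param overrides named list of values overriding the file.
#' @return A validated [RunSpec-class].
#' @export
readRunSpec <- function(path, overrides = list()) {
  if (!file.exists(path)) .configError("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)[[:space:]]*=[[:space:]]*(.*)$",
                                  lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad))
    .configError("cannot parse config line: '", bad[1], "'")
  vals <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
  unknown <- setdiff(names(vals), .configKeys)
  if (length(unknown))
    .configError("unknown config key(s): ", paste(unknown, collapse = ", "))
  unknownOv <- setdiff(names(overrides), .configKeys)
  if (length(unknownOv))
    .configError("unknown override key(s): ",
                 paste(unknownOv, collapse = ", "))
  vals[names(overrides)] <- overrides
  numKeys <- setdiff(.configKeys, c("mode", "preset", "out_dir"))
  for (k in intersect(names(vals), numKeys)) {
    v <- suppressWarnings(as.numeric(vals[[k]]))
    if (is.na(v)) .configError("config key '", k, "' must be numeric")
    vals[[k]] <- v
  }
  do.call(runSpec, vals)
}

#' Execute a run specification
#'
#' Runs the BD engine under the spec, writes the profile (long format and
#' per-scan files), the equilibrium fit report when in equilibrium mode,
#' optionally the Lamm-oracle comparison, and a machine-readable summary
#' (`summary.txt`, flat `key = value`) recording the full configuration,
#' seed and timings. Identical spec + seed give bitwise-identical outputs.
#'
#' @param spec a [RunSpec-class].
#' @param compareLamm also solve the Lamm equation and report the RMS
#'   deviation per scan (written to `lamm_rms.csv`).
#' @return Invisibly, a list with the profile, the fit (equilibrium mode
#'   only), the Lamm comparison (if requested) and the written file paths.
#' @export
runAUC <- function(spec, compareLamm = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(spec@outDir, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch({
    cm <- simulateCounts(spec@solute, spec@geometry, spec@run,
                         workers = spec@workers)
    prof <- countsToConcentration(cm)
    prof@rpm <- spec@run@rpm
    prof
  }, error = function(e)
    stop(errorCondition(paste0("simulation failed: ", conditionMessage(e)),
                        class = c("aucSolverError", "error"))))
  files <- c(profile = file.path(spec@outDir, "profile.csv"))
  writeProfile(res, files[["profile"]])
  files <- c(files, writeScans(res, spec@outDir))
  out <- list(profile = res)

  constants <- physicalConstants(spec@temperature)
  if (spec@mode == "equilibrium") {
    fit <- fitEquilibriumMass(res, spec@solute@buoyancy,
                              rpmToOmega(spec@run@rpm),
                              rMeniscus = spec@geometry@rMeniscus,
                              exclusion = spec@exclusion,
                              constants = constants)
    fitPath <- file.path(spec@outDir, "equilibrium_fit.txt")
    writeFitReport(fit, fitPath)
    files <- c(files, fit = fitPath)
    out$fit <- fit
  }
  if (compareLamm) {
    cmp <- tryCatch(
      compareToLamm(spec@solute, spec@geometry, spec@run,
                    exclusion = spec@exclusion),
      error = function(e)
        stop(errorCondition(paste0("Lamm solver failed: ",
                                   conditionMessage(e)),
                            class = c("aucSolverError", "error"))))
    rmsPath <- file.path(spec@outDir, "lamm_rms.csv")
    writeLines(c("scan,t_s,rms",
                 sprintf("%d,%.17g,%.17g", seq_along(cmp$perScan),
                         scanTimes(spec@run), cmp$perScan),
                 sprintf("pooled,,%.17g", cmp$pooled)), rmsPath)
    files <- c(files, lamm = rmsPath)
    out$lamm <- cmp
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  summaryPath <- file.path(spec@outDir, "summary.txt")
  writeLines(c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("aucBD"))),
    sprintf("mode = %s", spec@mode),
    sprintf("preset = %s", spec@preset),
    sprintf("s_svedberg = %.10g", spec@solute@s * 1e13),
    sprintf("d_cm2_per_s = %.10g", spec@solute@D),
    sprintf("mass_g_per_mol = %.10g", spec@solute@M),
    sprintf("buoyancy = %.10g", spec@solute@buoyancy),
    sprintf("rpm = %.10g", spec@run@rpm),
    sprintf("t_run_s = %.10g", spec@run@tRun),
    sprintf("n_part = %d", spec@run@nParticles),
    sprintf("n_r = %d", spec@geometry@nRadial),
    sprintf("n_steps = %d", spec@run@nSteps),
    sprintf("n_scans = %d", spec@run@nScans),
    sprintf("r_m_cm = %.10g", spec@geometry@rMeniscus),
    sprintf("r_b_cm = %.10g", spec@geometry@rBottom),
    sprintf("phi_rad = %.10g", spec@geometry@phi),
    sprintf("temperature_k = %.10g", spec@temperature),
    sprintf("seed = %d", spec@run@seed),
    sprintf("exclusion_fraction = %.10g", spec@exclusion),
    sprintf("workers = %d", spec@workers),
    sprintf("elapsed_s = %.3f", elapsed),
    if (!is.null(out$fit))
      sprintf("m_fit_g_per_mol = %.10g", out$fit@mFit),
    if (!is.null(out$lamm))
      sprintf("lamm_pooled_rms = %.10g", out$lamm$pooled)
  ), summaryPath)
  files <- c(files, summary = summaryPath)
  out$files <- files
  invisible(out)
}
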