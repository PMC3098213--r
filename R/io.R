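#' Read and write concentration profiles
#'
#' Two plain-text formats are supported, both with full double precision so
#' that write/read round-trips are exact:
#' * long format (comma-separated, header `scan,t_s,r_cm,c_over_c0`, one row
#'   per scan/radius pair) via `writeProfile()`;
#' * per-scan format (two space-separated columns `r_cm c_over_c0` under a
#'   one-line header `# t= <seconds> s rpm= <rpm>`) via `writeScans()`, one
#'   file per scan, for import into external AUC analysis tools.
#'
#' `readProfile()` accepts a long-format file or a vector of per-scan files
#' and reconstructs the [ConcentrationProfile-class].
#'
#' @param profile a [ConcentrationProfile-class].
#' @param path output file (long format) or input file(s).
#' @param dir,prefix output directory and file-name prefix for the per-scan
#'   writer; files are named `<prefix>_scan<j>.dat`.
#' @param rpm rotor speed stamped into per-scan headers; defaults to the
#'   profile's `rpm` slot (0 if unset).
#' @param provenance provenance label given to profiles read back in.
#' @return `writeProfile()` returns `path` invisibly; `writeScans()` the
#'   written file names invisibly; `readProfile()` a
#'   [ConcentrationProfile-class].
#' @examples
#' geom <- cellGeometry(nRadial = 10)
#' p <- equilibriumProfileAnalytic(geom, 14.3e3, 0.298, rpmToOmega(15000))
#' f <- tempfile(fileext = ".csv")
#' writeProfile(p, f)
#' identical(profileValues(readProfile(f)), profileValues(p))
#' @export
writeProfile <- function(profile, path) {
  g <- expand.grid(i = seq_along(profile@radii),
                   j = seq_along(profile@times))
  lines <- sprintf("%d,%.17g,%.17g,%.17g",
                   g$j, profile@times[g$j], profile@radii[g$i],
                   profile@values[cbind(g$i, g$j)])
  writeLines(c("scan,t_s,r_cm,c_over_c0", lines), path)
  invisible(path)
}

#' @rdname writeProfile
#' @export
writeScans <- function(profile, dir, prefix = "profile", rpm = NULL) {
  if (is.null(rpm)) rpm <- if (is.na(profile@rpm)) 0 else profile@rpm
  files <- character(length(profile@times))
  for (j in seq_along(profile@times)) {
    files[j] <- file.path(dir, sprintf("%s_scan%03d.dat", prefix, j))
    writeLines(c(sprintf("# t= %.17g s rpm= %.17g", profile@times[j], rpm),
                 sprintf("%.17g %.17g", profile@radii,
                         profile@values[, j])),
               files[j])
  }
  invisible(files)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path, provenance = "BD") {
  first <- readLines(path[1], n = 1L)
  if (startsWith(first, "scan,")) {
    d <- utils::read.csv(path[1], colClasses = "numeric")
    js <- sort(unique(d$scan))
    radii <- sort(unique(d$r_cm))
    times <- vapply(js, function(j) d$t_s[d$scan == j][1], numeric(1))
    vals <- matrix(NA_real_, length(radii), length(js))
    ij <- cbind(match(d$r_cm, radii), match(d$scan, js))
    vals[ij] <- d$c_over_c0
    rpm <- NA_real_
  } else {
    scans <- lapply(path, function(f) {
      hdr <- readLines(f, n = 1L)
      m <- regmatches(hdr, regexec(
        "^# t= ([-+0-9.eE]+) s rpm= ([-+0-9.eE]+)", hdr))[[1]]
      if (length(m) != 3) stop("unrecognized per-scan header in ", f)
      d <- utils::read.table(f, col.names = c("r", "c"),
                             colClasses = "numeric")
      list(t = as.numeric(m[2]), rpm = as.numeric(m[3]), r = d$r, c = d$c)
    })
    radii <- scans[[1]]$r
    times <- vapply(scans, `[[`, numeric(1), "t")
    ord <- order(times)
    scans <- scans[ord]
    times <- times[ord]
    vals <- vapply(scans, function(s) {
      if (!isTRUE(all.equal(s$r, radii))) stop("scan grids differ")
      s$c
    }, numeric(length(radii)))
    vals <- matrix(vals, nrow = length(radii))
    rpm <- scans[[1]]$rpm
  }
  new("ConcentrationProfile", radii = radii, times = times, values = vals,
      provenance = provenance, c0 = 1, rpm = rpm)
}

#' Write an equilibrium fit report
#'
#' One-line delimited text report (`key = value` pairs, one per line) with
#' the recovered molar mass, slope, intercept, fit window, point count,
#' residual RMS and the late-scan convergence diagnostic.
#'
#' @param fit an [EquilibriumFit-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fit, path) {
  writeLines(c(
    sprintf("m_fit_g_per_mol = %.10g", fit@mFit),
    sprintf("slope_per_cm2 = %.10g", fit@slope),
    sprintf("intercept = %.10g", fit@intercept),
    sprintf("window_cm = %.6f %.6f", fit@window[1], fit@window[2]),
    sprintf("n_points = %d", fit@nPoints),
    sprintf("residual_rms = %.6g", fit@residualRMS),
    sprintf("last_scan_change = %.6g", fit@convergence)
  ), path)
  invisible(path)
}

#' Export trajectories as delimited text
#'
#' Long format with header `particle,t_s,r_cm`, one row per particle and
#' recorded time (the initial position at t = 0 and every scan).
#'
#' @param records trajectory matrix from [simulateTrajectories()].
#' @param times recorded times (s), one per row of `records`.
#' @param particles particle indices, one per column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(records, times, particles, path) {
  if (nrow(records) != length(times)) stop("one time per row required")
  if (ncol(records) != length(particles))
    stop("one particle index per column required")
  g <- expand.grid(j = seq_along(times), k = seq_along(particles))
  lines <- sprintf("%d,%.17g,%.17g", particles[g$k], times[g$j],
                   records[cbind(g$j, g$k)])
  writeLines(c("particle,t_s,r_cm", lines), path)
  invisible(path)
}
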