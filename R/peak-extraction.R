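# EIC peak-height extraction with internal-standard RT recalibration.
#
# Per sample: locate internal-standard apexes inside a 0.20-min window
# centered on their expected retention times, fit a quadratic
# expected -> observed RT recalibration, then extract the maximum intensity
# inside a 0.20-min window centered on each target's recalibrated RT as its
# peak height. No smoothing or integration is applied; peak height, apex RT
# and signal-to-noise are reported per (sample, ion).

#' Apex of an internal standard inside its search window
#'
#' The observed RT is the time point of maximum intensity inside
#' `expected_rt` +/- `window/2`; ties resolve to the earliest RT. An all-zero
#' window means the standard was not detected (excluded from the
#' recalibration fit); an apex sitting exactly on a window edge is returned
#' but flagged low-confidence.
#'
#' @param rt Strictly increasing RT grid, minutes.
#' @param intensity Nonnegative intensities on the grid.
#' @param expected_rt Expected apex RT, minutes.
#' @param window Total window width, minutes.
#' @param refine Refine the apex below the grid resolution by a parabolic
#'   interpolation of log intensity (baseline-subtracted) through the grid
#'   maximum and its neighbors. Exact for a Gaussian peak on a constant
#'   baseline; used for the internal standards feeding the RT
#'   recalibration, where grid quantization would otherwise dominate the
#'   quadratic fit error.
#' @return List with `apex_rt`, `detected`, `on_boundary`.
#' @export
observed_standard_rt <- function(rt, intensity, expected_rt, window = 0.20,
                                 refine = FALSE) {
  w <- window_indices(rt, expected_rt, window)
  y <- intensity[w]
  if (all(y == 0))
    return(list(apex_rt = NA_real_, detected = FALSE, on_boundary = FALSE))
  i <- w[which.max(y)]  # first maximum = earliest RT on ties
  on_boundary <- i == w[1] || i == w[length(w)]
  apex <- rt[i]
  if (refine && !on_boundary) {
    base <- stats::median(intensity)
    y3 <- intensity[(i - 1):(i + 1)] - base
    if (all(y3 > 0)) {
      ly <- log(y3)
      denom <- ly[1] - 2 * ly[2] + ly[3]
      if (denom < 0) {
        delta <- 0.5 * (ly[1] - ly[3]) / denom
        if (abs(delta) <= 0.5) apex <- rt[i] + delta * (rt[i + 1] - rt[i])
      }
    }
  }
  list(apex_rt = apex, detected = TRUE, on_boundary = on_boundary)
}

# Grid indices falling inside center +/- window/2 (closed; small epsilon
# absorbs representation error on regular grids).
window_indices <- function(rt, center, window) {
  if (length(rt) != length(rt) || length(rt) < 1L) abort("empty trace")
  eps <- 1e-9
  idx <- which(rt >= center - window / 2 - eps &
               rt <= center + window / 2 + eps)
  if (!length(idx))
    abort("window [%.4f, %.4f] does not intersect the RT grid",
          center - window / 2, center + window / 2)
  idx
}

#' Fit the quadratic retention-time recalibration
#'
#' Least-squares fit of `observed = a expected^2 + b expected + c` on the
#' internal standards of one sample. The model maps the database's expected
#' RTs onto the sample's chromatographic time axis.
#'
#' @param expected,observed Paired RTs (minutes) of the detected internal
#'   standards; pairs with a missing observation are dropped.
#' @return An `rt_calibration`: coefficients `a`, `b`, `c`, the pairs used,
#'   and per-standard residuals.
#' @export
fit_rt_recalibration <- function(expected, observed) {
  keep <- is.finite(expected) & is.finite(observed)
  expected <- expected[keep]; observed <- observed[keep]
  if (length(expected) < 3L)
    abort("insufficient standards: %d detected, need at least 3",
          length(expected))
  if (length(unique(expected)) < 3L)
    abort("rank-deficient design: expected RTs must take >= 3 distinct values")
  X <- cbind(1, expected, expected^2)
  fit <- stats::lm.fit(X, observed)
  if (fit$rank < 3L) abort("rank-deficient design in RT recalibration")
  cf <- unname(fit$coefficients)
  structure(list(a = cf[3], b = cf[2], c = cf[1],
                 expected = expected, observed = observed,
                 residuals = unname(fit$residuals)),
            class = "rt_calibration")
}

#' Apply an RT recalibration to expected retention times
#'
#' @param calibration An [fit_rt_recalibration()] result (or `NULL` for the
#'   identity mapping).
#' @param expected_rt Expected RTs, minutes.
#' @return Recalibrated RTs, minutes.
#' @export
calibrate_rt <- function(calibration, expected_rt) {
  if (is.null(calibration)) return(expected_rt)
  stopifnot(inherits(calibration, "rt_calibration"))
  calibration$a * expected_rt^2 + calibration$b * expected_rt + calibration$c
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf(
    "<rt_calibration> observed = %.3g rt^2 + %.4f rt + %.4f (%d standards, max |resid| %.4g min)\n",
    x$a, x$b, x$c, length(x$expected), max(abs(x$residuals))))
  invisible(x)
}

#' Extract a peak height in a recalibrated window
#'
#' Peak height is the maximum intensity inside `calibrated_rt` +/-
#' `window/2`; the apex is the earliest grid point attaining it.
#'
#' @param rt,intensity EIC trace.
#' @param calibrated_rt Window center, minutes.
#' @param window Total window width, minutes.
#' @return List with `peak_height`, `apex_rt`, `window_lo`, `window_hi`,
#'   `on_boundary`.
#' @export
extract_peak <- function(rt, intensity, calibrated_rt, window = 0.20) {
  w <- window_indices(rt, calibrated_rt, window)
  i <- w[which.max(intensity[w])]
  list(peak_height = intensity[i], apex_rt = rt[i],
       window_lo = calibrated_rt - window / 2,
       window_hi = calibrated_rt + window / 2,
       on_boundary = i == w[1] || i == w[length(w)])
}

#' Signal-to-noise of a peak within its EIC
#'
#' Peak height divided by the median intensity over the full EIC span. A
#' zero median yields an infinite SNR with a flag rather than an error.
#'
#' @param intensity Full-span EIC intensities (must be nonnegative).
#' @param peak_height Extracted peak height.
#' @return List with `snr` and `median_zero`.
#' @export
signal_to_noise <- function(intensity, peak_height) {
  if (!length(intensity)) abort("empty trace")
  if (any(intensity < 0)) abort("negative intensities: corrupt input")
  med <- stats::median(intensity)
  if (med == 0) return(list(snr = Inf, median_zero = TRUE))
  list(snr = peak_height / med, median_zero = FALSE)
}

#' Extract a raw peak-height matrix from an EIC set
#'
#' Runs the full per-sample procedure: internal-standard apex location,
#' quadratic RT recalibration (per sample, pooling standards of both modes),
#' windowed peak extraction and signal-to-noise for every target ion. Blanks
#' carry no internal standards and take the identity calibration; samples
#' with fewer than 3 detected standards fall back to identity with a flag.
#'
#' @param eics An `eic_set` (from [simulate_eics()] or [read_run()]).
#' @param window Peak-search window width, minutes.
#' @return A [feature_matrix()].
#' @export
extract_features <- function(eics, window = 0.20) {
  stopifnot(inherits(eics, "eic_set"))
  db <- eics$db; plan <- eics$plan
  is_idx <- which(db$is_internal_standard)
  n_ion <- nrow(db); n_sample <- nrow(plan)

  heights <- apex <- snr <- matrix(
    NA_real_, n_sample, n_ion, dimnames = list(plan$sample_id, db$ion_id))
  boundary <- matrix(FALSE, n_sample, n_ion,
                     dimnames = list(plan$sample_id, db$ion_id))
  calib <- data.frame(sample_id = plan$sample_id, a = 0, b = 1, c = 0,
                      n_standards = 0L, method = "identity",
                      stringsAsFactors = FALSE)

  for (i in seq_len(n_sample)) {
    sid <- plan$sample_id[i]
    m <- eics$intensity[[sid]]
    cal <- NULL
    if (plan$sample_type[i] != "blank") {
      obs <- rep(NA_real_, length(is_idx))
      for (k in seq_along(is_idx)) {
        j <- is_idx[k]
        o <- observed_standard_rt(db$expected_rt[j] + eics$offsets, m[, j],
                                  db$expected_rt[j], window, refine = TRUE)
        if (o$detected) obs[k] <- o$apex_rt
      }
      if (sum(is.finite(obs)) >= 3L) {
        cal <- fit_rt_recalibration(db$expected_rt[is_idx], obs)
        calib$a[i] <- cal$a; calib$b[i] <- cal$b; calib$c[i] <- cal$c
        calib$n_standards[i] <- length(cal$expected)
        calib$method[i] <- "quadratic"
      }
    }
    crt <- calibrate_rt(cal, db$expected_rt)
    for (j in seq_len(n_ion)) {
      rt <- db$expected_rt[j] + eics$offsets
      pk <- extract_peak(rt, m[, j], crt[j], window)
      heights[i, j] <- pk$peak_height
      apex[i, j] <- pk$apex_rt
      boundary[i, j] <- pk$on_boundary
      snr[i, j] <- signal_to_noise(m[, j], pk$peak_height)$snr
    }
  }

  feature_matrix(heights, plan, db, apex_rt = apex, snr = snr,
                 boundary = boundary, calibrations = calib,
                 provenance = sprintf("extracted: window=%.2f min", window))
}

#' Construct a feature matrix
#'
#' The samples x target-ions peak-height table with sample annotations
#' (type, batch, injection order) and ion annotations joined from the
#' database, plus optional apex RT, SNR and boundary-flag matrices. Missing
#' measurements are explicit `NA`s, never zeros.
#'
#' @param heights Numeric matrix, samples x ions, dimnames =
#'   (sample_id, ion_id).
#' @param plan Injection plan covering every row.
#' @param db Ion database covering every column.
#' @param apex_rt,snr,boundary Optional same-shape matrices.
#' @param calibrations Optional per-sample RT calibration table.
#' @param provenance Character vector describing processing state.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(heights, plan, db, apex_rt = NULL, snr = NULL,
                           boundary = NULL, calibrations = NULL,
                           provenance = character()) {
  stopifnot(is.matrix(heights), !is.null(rownames(heights)),
            !is.null(colnames(heights)))
  missing_samples <- setdiff(rownames(heights), plan$sample_id)
  if (length(missing_samples))
    abort("sample(s) absent from the injection plan: %s",
          paste(missing_samples, collapse = ", "))
  missing_ions <- setdiff(colnames(heights), db$ion_id)
  if (length(missing_ions))
    abort("ion(s) absent from the database: %s",
          paste(missing_ions, collapse = ", "))
  samples <- as.data.frame(plan)[match(rownames(heights), plan$sample_id), ]
  rownames(samples) <- NULL
  ions <- as.data.frame(db)[match(colnames(heights), db$ion_id), ]
  rownames(ions) <- NULL
  if (is.null(boundary))
    boundary <- matrix(FALSE, nrow(heights), ncol(heights),
                       dimnames = dimnames(heights))
  structure(list(heights = heights, apex_rt = apex_rt, snr = snr,
                 boundary = boundary, samples = samples, ions = ions,
                 calibrations = calibrations,
                 provenance = as.character(provenance)),
            class = "feature_matrix")
}

#' Assemble a feature matrix from long-format measurements
#'
#' @param measurements Data frame with `sample_id`, `ion_id`, `peak_height`
#'   and optionally `apex_rt`, `snr`, `on_boundary`; at most one row per
#'   (sample, ion). Absent combinations become explicit `NA`s.
#' @param plan Injection plan; every measured sample must appear in it.
#' @param db Ion database; every measured ion must appear in it.
#' @return A [feature_matrix()] covering all plan samples and db ions.
#' @export
assemble_feature_matrix <- function(measurements, plan, db) {
  req <- c("sample_id", "ion_id", "peak_height")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols))
    abort("measurements are missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  bad <- setdiff(measurements$sample_id, plan$sample_id)
  if (length(bad))
    abort("sample(s) absent from the injection plan: %s",
          paste(unique(bad), collapse = ", "))
  bad <- setdiff(measurements$ion_id, db$ion_id)
  if (length(bad))
    abort("ion(s) absent from the database: %s",
          paste(unique(bad), collapse = ", "))
  key <- paste(measurements$sample_id, measurements$ion_id)
  if (anyDuplicated(key))
    abort("duplicate (sample, ion) measurement(s): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))

  dn <- list(plan$sample_id, db$ion_id)
  fill <- function(col, default = NA_real_) {
    m <- matrix(default, nrow(plan), nrow(db), dimnames = dn)
    if (col %in% names(measurements))
      m[cbind(measurements$sample_id, measurements$ion_id)] <-
        measurements[[col]]
    m
  }
  feature_matrix(fill("peak_height"), plan, db,
                 apex_rt = fill("apex_rt"), snr = fill("snr"),
                 boundary = fill("on_boundary", FALSE),
                 provenance = "assembled from long-format measurements")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d ions (%s)\n",
              nrow(x$heights), ncol(x$heights),
              if (length(x$provenance))
                x$provenance[length(x$provenance)] else "raw"))
  invisible(x)
}

#' Write a feature matrix to CSV
#'
#' The matrix file has `sample_id` as its first column and one column per
#' ion, preceded by `#`-prefixed provenance header lines; sample and ion
#' annotations go to `<prefix>_samples.csv` / `<prefix>_ions.csv` sidecars.
#'
#' @param fm A [feature_matrix()].
#' @param prefix Path prefix for the three files.
#' @return The matrix file path, invisibly.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  path <- paste0(prefix, "_matrix.csv")
  con <- file(path, "w")
  on.exit(close(con))
  for (line in fm$provenance) writeLines(paste("#", line), con)
  df <- data.frame(sample_id = rownames(fm$heights), stringsAsFactors = FALSE)
  for (j in colnames(fm$heights)) df[[j]] <- format_full(fm$heights[, j])
  df[df == "NA"] <- ""
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  utils::write.csv(fm$samples, paste0(prefix, "_samples.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(fm$ions, paste0(prefix, "_ions.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param prefix Path prefix used at write time.
#' @param plan,db Optional plan / database; when omitted they are rebuilt
#'   from the annotation sidecars.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(prefix, plan = NULL, db = NULL) {
  path <- paste0(prefix, "_matrix.csv")
  lines <- readLines(path)
  prov <- sub("^# ", "", lines[startsWith(lines, "#")])
  tab <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                         check.names = FALSE, na.strings = "")
  heights <- as.matrix(tab[, -1, drop = FALSE])
  rownames(heights) <- tab$sample_id
  if (is.null(plan)) {
    plan <- utils::read.csv(paste0(prefix, "_samples.csv"),
                            stringsAsFactors = FALSE, na.strings = "")
    plan$duplicate_of <- as.character(plan$duplicate_of)
    plan <- structure(plan, class = c("injection_plan", "data.frame"),
                      n_batches = max(plan$batch))
  }
  if (is.null(db)) {
    ions <- utils::read.csv(paste0(prefix, "_ions.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    ions$mz <- as.numeric(ions$mz)
    ions$expected_rt <- as.numeric(ions$expected_rt)
    ions$is_internal_standard <- ions$is_internal_standard %in%
      c("TRUE", "true", "1")
    ions$is_known <- ions$is_known %in% c("TRUE", "true", "1")
    ions$inchikey[is.na(ions$inchikey)] <- ""
    db <- ion_database(ions, min_internal_standards = 0L)
  }
  feature_matrix(heights, plan, db, provenance = prov)
}
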