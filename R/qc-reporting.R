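# Technical-validation suite: duplicate paired t-tests, PCA overview, blank
# carryover checks, fold-change utilities, RSD summaries and histograms.

#' Paired t-tests on duplicate study samples
#'
#' Classical paired t statistic per ion on log10 peak heights across the
#' replicate pairs (a multiplicative noise model makes log differences
#' approximately normal), with a two-sided p-value. Pairs with a missing or
#' nonpositive member are dropped per ion; zero-variance differences are
#' reported as degenerate with p = 1.
#'
#' @param fm A [feature_matrix()] (or plain samples x ions matrix).
#' @param pairs Data frame with columns `original` and `replicate`
#'   (sample ids). Defaults to the pairs recorded in the plan's
#'   `duplicate_of` column.
#' @param log_transform Test on log10 heights (default) or raw heights.
#' @param alpha Significance level for the summary fraction.
#' @return Data frame per ion (`ion_id`, `n_pairs`, `t`, `p`, `degenerate`)
#'   with `attr(, "fraction_nonsignificant")` = fraction of ions with
#'   p > `alpha`.
#' @export
duplicate_paired_ttest <- function(fm, pairs = NULL, log_transform = TRUE,
                                   alpha = 0.05) {
  heights <- if (inherits(fm, "feature_matrix")) fm$heights else fm
  if (is.null(pairs)) {
    if (!inherits(fm, "feature_matrix"))
      abort("pairs must be given when fm is a plain matrix")
    dup <- fm$samples[!is.na(fm$samples$duplicate_of), , drop = FALSE]
    pairs <- data.frame(original = dup$duplicate_of,
                        replicate = dup$sample_id, stringsAsFactors = FALSE)
  }
  if (!nrow(pairs)) abort("no duplicate pairs available")
  bad <- setdiff(c(pairs$original, pairs$replicate), rownames(heights))
  if (length(bad))
    abort("pair member(s) absent from the matrix: %s",
          paste(unique(bad), collapse = ", "))

  out <- lapply(colnames(heights), function(ion) {
    a <- heights[pairs$original, ion]
    b <- heights[pairs$replicate, ion]
    ok <- is.finite(a) & is.finite(b)
    if (log_transform) ok <- ok & a > 0 & b > 0
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 2L)
      return(data.frame(ion_id = ion, n_pairs = n, t = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    d <- if (log_transform) log10(b) - log10(a) else b - a
    s <- stats::sd(d)
    if (s == 0)
      return(data.frame(ion_id = ion, n_pairs = n, t = NA_real_, p = 1,
                        degenerate = TRUE))
    t_stat <- mean(d) / (s / sqrt(n))
    data.frame(ion_id = ion, n_pairs = n, t = t_stat,
               p = 2 * stats::pt(-abs(t_stat), n - 1), degenerate = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "fraction_nonsignificant") <-
    mean(res$p > alpha, na.rm = TRUE)
  res
}

#' PCA overview of a feature matrix
#'
#' Singular value decomposition of the log10-transformed, column-centered
#' (unscaled) peak-height matrix over non-blank samples. Ions containing
#' nonpositive or missing values are dropped (and reported). A constant
#' matrix yields zero variance, not an error.
#'
#' @param fm A [feature_matrix()].
#' @param log_transform log10-transform heights first (default TRUE).
#' @param n_components Number of components to retain in the scores.
#' @return List with `variance_explained` (percent per component),
#'   `scores` (data frame with sample annotations), `dropped_ions`.
#' @export
pca_overview <- function(fm, log_transform = TRUE, n_components = 5L) {
  stopifnot(inherits(fm, "feature_matrix"))
  rows <- fm$samples$sample_type != "blank"
  X <- fm$heights[rows, , drop = FALSE]
  if (nrow(X) < 3L || ncol(X) < 2L)
    abort("PCA needs at least 3 samples and 2 ions")
  usable <- apply(X, 2L, function(col)
    all(is.finite(col)) && (!log_transform || all(col > 0)))
  dropped <- colnames(X)[!usable]
  X <- X[, usable, drop = FALSE]
  if (ncol(X) < 2L) abort("fewer than 2 usable ions for PCA")
  if (log_transform) X <- log10(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  var_comp <- sv$d^2 / (nrow(X) - 1)
  total <- sum(var_comp)
  k <- min(n_components, length(sv$d))
  scores <- as.data.frame(sv$u[, seq_len(k), drop = FALSE] %*%
                            diag(sv$d[seq_len(k)], k))
  names(scores) <- paste0("PC", seq_len(k))
  scores <- cbind(fm$samples[rows, c("sample_id", "sample_type", "batch",
                                     "injection_order")], scores)
  rownames(scores) <- NULL
  list(variance_explained = if (total > 0) 100 * var_comp / total
                            else rep(0, length(var_comp)),
       total_variance = total, scores = scores, dropped_ions = dropped)
}

#' Blank carryover check
#'
#' Per blank, the ratio of its baseline-subtracted total-ion signal (summed
#' over all ions and RT points, each trace's median taken as its baseline)
#' to the same quantity of the immediately preceding QC injection. Blanks
#' with no preceding QC are skipped and logged.
#'
#' @param eics An `eic_set`.
#' @param threshold Flagging threshold on the ratio (default 5 percent).
#' @return Data frame per blank: `blank_id`, `qc_id`, `ratio`, `flagged`;
#'   skipped blanks carry `NA` ratios.
#' @export
carryover_check <- function(eics, threshold = 0.05) {
  stopifnot(inherits(eics, "eic_set"))
  plan <- eics$plan
  blanks <- which(plan$sample_type == "blank")
  if (!length(blanks)) abort("no blank injections in the plan")
  tic <- function(sid) {
    m <- eics$intensity[[sid]]
    sum(apply(m, 2L, function(y) sum(pmax(0, y - stats::median(y)))))
  }
  out <- lapply(blanks, function(i) {
    prev_qc <- which(plan$sample_type == "qc" &
                       plan$injection_order < plan$injection_order[i])
    if (!length(prev_qc))
      return(data.frame(blank_id = plan$sample_id[i], qc_id = NA_character_,
                        ratio = NA_real_, flagged = NA))
    qi <- prev_qc[which.max(plan$injection_order[prev_qc])]
    q <- tic(plan$sample_id[qi])
    r <- if (q > 0) tic(plan$sample_id[i]) / q else NA_real_
    data.frame(blank_id = plan$sample_id[i], qc_id = plan$sample_id[qi],
               ratio = r, flagged = if (is.na(r)) NA else r > threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fold change between two group means
#'
#' @param mean_a,mean_b Positive group means (e.g. mean peak heights).
#' @return List with `fold` (`max/min`, >= 1) and `direction`
#'   (`"decrease"` when `mean_a < mean_b`, `"increase"` when greater,
#'   `"none"` when equal).
#' @examples
#' fold_change(25000, 75000)  # 3-fold decrease
#' @export
fold_change <- function(mean_a, mean_b) {
  if (!is.finite(mean_a) || !is.finite(mean_b) || mean_a <= 0 || mean_b <= 0)
    abort("fold change requires positive means")
  list(fold = max(mean_a, mean_b) / min(mean_a, mean_b),
       direction = if (mean_a < mean_b) "decrease"
                   else if (mean_a > mean_b) "increase" else "none")
}

#' Histogram of per-ion QC RSDs
#'
#' Right-open bins of `bin_width` percent over `[0, max]`, plus the fraction
#' of ions below 20 percent RSD (the conventional reproducibility summary).
#'
#' @param rsd_values Finite per-ion RSDs, percent.
#' @param bin_width Bin width, percent.
#' @return List with `breaks`, `counts`, `fraction_below_20`.
#' @export
rsd_histogram <- function(rsd_values, bin_width = 5) {
  rsd_values <- rsd_values[is.finite(rsd_values)]
  if (!length(rsd_values)) abort("no finite RSD values")
  top <- max(bin_width, ceiling(max(rsd_values) / bin_width) * bin_width)
  breaks <- seq(0, top, by = bin_width)
  bin <- pmin(findInterval(rsd_values, breaks), length(breaks) - 1L)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  list(breaks = breaks, counts = counts,
       fraction_below_20 = mean(rsd_values < 20))
}

#' Assemble the technical-validation report
#'
#' Bundles the QC analyses over one processed run: per-ion QC RSD before
#' and after normalization, internal-standard RSD per mode, duplicate
#' paired t-tests, PCA variance overview, blank carryover ratios and the
#' QC RSD histogram.
#'
#' @param raw_fm Raw [feature_matrix()].
#' @param norm_fm Normalized [feature_matrix()].
#' @param eics Optional `eic_set` for the carryover check.
#' @param carryover_threshold Flagging threshold for blank/QC TIC ratios.
#' @return A `qc_report` list.
#' @export
qc_report <- function(raw_fm, norm_fm, eics = NULL,
                      carryover_threshold = 0.05) {
  pre <- qc_rsd(raw_fm)
  post <- qc_rsd(norm_fm)
  istd <- norm_fm$ions$is_internal_standard
  is_table <- data.frame(
    ion_id = norm_fm$ions$ion_id[istd],
    mode = norm_fm$ions$mode[istd],
    pre_rsd = unname(pre[norm_fm$ions$ion_id[istd]]),
    post_rsd = unname(post[norm_fm$ions$ion_id[istd]]),
    stringsAsFactors = FALSE)
  dup <- tryCatch(duplicate_paired_ttest(norm_fm), error = function(e) NULL)
  structure(list(
    qc_rsd_pre = pre, qc_rsd_post = post,
    internal_standard_rsd = is_table,
    duplicate_ttest = dup,
    fraction_nonsignificant = if (is.null(dup)) NA_real_
                              else attr(dup, "fraction_nonsignificant"),
    pca = pca_overview(norm_fm),
    carryover = if (is.null(eics)) NULL
                else carryover_check(eics, carryover_threshold),
    histogram = rsd_histogram(post[!istd][is.finite(post[!istd])])),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  analyte QC RSD < 20%%: %.1f%% of ions (post-normalization)\n",
              100 * x$histogram$fraction_below_20))
  cat(sprintf("  internal standards: %d, median post RSD %.2f%%\n",
              nrow(x$internal_standard_rsd),
              stats::median(x$internal_standard_rsd$post_rsd, na.rm = TRUE)))
  if (!is.na(x$fraction_nonsignificant))
    cat(sprintf("  duplicate t-tests nonsignificant (p > 0.05): %.1f%%\n",
                100 * x$fraction_nonsignificant))
  cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$pca$variance_explained[1], x$pca$variance_explained[2]))
  if (!is.null(x$carryover))
    cat(sprintf("  carryover: max blank/QC ratio %.4f (%d flagged)\n",
                max(x$carryover$ratio, na.rm = TRUE),
                sum(x$carryover$flagged, na.rm = TRUE)))
  invisible(x)
}

#' Write a QC report to disk
#'
#' Emits CSV tables (per-ion RSD, internal-standard RSD, duplicate t-tests,
#' PCA scores and variance, carryover ratios, histogram bins) and a
#' markdown summary.
#'
#' @param report A [qc_report()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_qc_report <- function(report, out_dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  w(data.frame(ion_id = names(report$qc_rsd_pre),
               pre_rsd = unname(report$qc_rsd_pre),
               post_rsd = unname(report$qc_rsd_post)), "qc_rsd.csv")
  w(report$internal_standard_rsd, "internal_standard_rsd.csv")
  if (!is.null(report$duplicate_ttest))
    w(report$duplicate_ttest, "duplicate_ttest.csv")
  w(report$pca$scores, "pca_scores.csv")
  w(data.frame(component = seq_along(report$pca$variance_explained),
               variance_explained = report$pca$variance_explained),
    "pca_variance.csv")
  if (!is.null(report$carryover)) w(report$carryover, "carryover.csv")
  w(data.frame(bin_lo = utils::head(report$histogram$breaks, -1),
               bin_hi = utils::head(report$histogram$breaks, -1) +
                 diff(report$histogram$breaks)[1],
               count = report$histogram$counts), "rsd_histogram.csv")

  md <- c("# Technical validation summary", "",
          sprintf("- Ions with post-normalization QC RSD < 20%%: %.1f%%",
                  100 * report$histogram$fraction_below_20),
          sprintf("- Internal standards tracked: %d (median post RSD %.2f%%)",
                  nrow(report$internal_standard_rsd),
                  stats::median(report$internal_standard_rsd$post_rsd,
                                na.rm = TRUE)),
          if (!is.na(report$fraction_nonsignificant))
            sprintf("- Duplicate paired t-tests with p > 0.05: %.1f%%",
                    100 * report$fraction_nonsignificant),
          sprintf("- PC1 / PC2 variance explained: %.1f%% / %.1f%%",
                  report$pca$variance_explained[1],
                  report$pca$variance_explained[2]),
          if (!is.null(report$carryover))
            sprintf("- Max blank/QC carryover ratio: %.4f",
                    max(report$carryover$ratio, na.rm = TRUE)))
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
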