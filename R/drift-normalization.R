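# QC-anchored LOESS drift correction and cross-batch median normalization.
#
# Per ion and batch, a degree-1 (local linear, tricube weights) LOESS curve
# is fitted to QC peak heights against injection order; every sample in the
# batch is divided by the curve's prediction at its injection order and
# re-anchored to the batch QC median, so the correction is multiplicative
# and scale-preserving. The LOESS span is chosen per curve by leave-one-out
# cross validation. Batches are then equalized per ion so each batch's QC
# median matches the global QC median. Performance is scored by a k-fold
# cross-validated QC RSD in which the correction models are refit without
# the held-out QCs.

DEFAULT_SPAN_GRID <- seq(0.3, 1.0, by = 0.1)

#' Local (LOESS) prediction of QC heights against injection order
#'
#' Degree-1 LOESS with tricube weights over the span-fraction nearest
#' neighbors. Evaluation points beyond the fitted range are clamped to the
#' boundary fit value. Spans whose neighborhood would contain fewer than 3
#' points are rejected (the local linear fit is unreliable there).
#'
#' @param x Predictor (injection orders), >= 4 points.
#' @param y Response (QC peak heights).
#' @param span Neighborhood fraction in (0, 1].
#' @param x_new Evaluation points.
#' @return Predicted heights at `x_new`.
#' @export
loess_predict <- function(x, y, span, x_new) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  if (length(x) < 4L)
    abort("need at least 4 points for a LOESS fit (got %d)", length(x))
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    abort("span must be in (0, 1]")
  if (floor(span * length(x)) < 3L)
    abort("span %.2f leaves fewer than 3 neighbors for %d points",
          span, length(x))
  if (length(unique(x)) < 2L) abort("degenerate x: all values equal")
  fit <- suppressWarnings(stats::loess(
    y ~ x, data = data.frame(x = x, y = y), span = span, degree = 1,
    family = "gaussian", control = stats::loess.control(surface = "direct")))
  xc <- pmin(pmax(x_new, min(x)), max(x))  # clamp: no extrapolation
  as.numeric(suppressWarnings(stats::predict(fit,
                                             newdata = data.frame(x = xc))))
}

#' Select the LOESS span by leave-one-out cross validation
#'
#' Scans a span grid, scoring each span by the mean squared leave-one-out
#' prediction error; ties (within 1e-12) resolve toward the largest span
#' (the smoother curve). Spans that cannot be fitted (neighborhood too
#' small) score infinitely.
#'
#' @param x,y Points (>= 5 for a meaningful LOO).
#' @param span_grid Candidate spans.
#' @return List with `span` (the winner) and `loo_mse` (named per-candidate
#'   scores).
#' @export
select_span_loocv <- function(x, y, span_grid = DEFAULT_SPAN_GRID) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  if (length(x) < 5L)
    abort("need at least 5 points for LOO span selection (got %d)", length(x))
  if (length(unique(x)) < 2L) abort("degenerate x: all values equal")
  mse <- vapply(span_grid, function(sp) {
    err <- vapply(seq_along(x), function(i) {
      p <- tryCatch(loess_predict(x[-i], y[-i], sp, x[i]),
                    error = function(e) NA_real_)
      if (is.finite(p)) (p - y[i])^2 else Inf
    }, numeric(1))
    mean(err)
  }, numeric(1))
  names(mse) <- format(span_grid)
  if (all(!is.finite(mse)))
    abort("no candidate span is feasible for %d points", length(x))
  best <- min(mse[is.finite(mse)])
  winner <- max(span_grid[is.finite(mse) & mse <= best + 1e-12])
  list(span = winner, loo_mse = mse)
}

# One ion-batch correction model fitted on QC (x, y). Returns a predictor
# function plus audit fields. Falls back to the batch-median model when too
# few QCs are available, when no span is feasible, or when a prediction is
# nonpositive while the anchor median is positive. The anchor constant is
# median(y) / median(y / prediction at QC positions), which makes the
# corrected within-batch QC median equal the raw one exactly (with a
# perfect fit the ratio term is 1 and the anchor is just median(y)).
fit_qc_drift_model <- function(x, y, span_grid, x_eval) {
  med_y <- stats::median(y)
  fallback <- function(reason) list(
    predict = function(x_new) rep(med_y, length(x_new)),
    method = "median_fallback", span = NA_real_, reason = reason,
    anchor = med_y)
  if (length(x) < 4L) return(fallback("fewer than 4 usable QCs"))
  sel <- if (length(x) >= 5L)
    tryCatch(select_span_loocv(x, y, span_grid)$span,
             error = function(e) NA_real_)
  else 1.0  # 4 QCs: no meaningful LOO, use the smoothest span
  if (is.na(sel)) return(fallback("no feasible LOESS span"))
  pred <- tryCatch(loess_predict(x, y, sel, x_eval),
                   error = function(e) NULL)
  pred_qc <- tryCatch(loess_predict(x, y, sel, x),
                      error = function(e) NULL)
  if (is.null(pred) || is.null(pred_qc) || any(!is.finite(pred)) ||
      (med_y > 0 && any(pred <= 0)))
    return(fallback("nonpositive or non-finite LOESS prediction"))
  ratio_med <- stats::median(y / pred_qc)
  anchor <- if (is.finite(ratio_med) && ratio_med > 0) med_y / ratio_med
            else med_y
  list(predict = function(x_new) loess_predict(x, y, sel, x_new),
       predicted_eval = pred, method = "loess", span = sel,
       reason = "", anchor = anchor)
}

#' Correct within-batch intensity drift using QC-anchored LOESS
#'
#' For each ion and batch, fits LOESS to QC peak heights versus injection
#' order (span by LOO-CV) and rescales every non-blank sample by
#' `median(QC heights in batch) / prediction(injection order)`. QCs flagged
#' apex-on-boundary or missing are excluded from the fits but still
#' corrected. Ion-batches with fewer than 4 usable QCs, or with nonpositive
#' predictions, fall back to the batch-median model (no within-batch
#' correction) and are audited as such. Blanks are never used in, nor
#' altered by, the correction.
#'
#' @param fm A raw [feature_matrix()].
#' @param span_grid Candidate LOESS spans.
#' @return List with `matrix` (corrected [feature_matrix()]) and `audit`
#'   (per ion-batch: method, span, usable QC count, pre/post QC RSD,
#'   correction-factor range).
#' @export
correct_batch_drift <- function(fm, span_grid = DEFAULT_SPAN_GRID) {
  stopifnot(inherits(fm, "feature_matrix"))
  plan <- fm$samples
  if (!any(plan$sample_type == "qc")) abort("no QC samples in the plan")
  for (b in unique(plan$batch))
    if (!any(plan$sample_type == "qc" & plan$batch == b))
      abort("batch %s contains no QC injections", b)

  heights <- fm$heights
  corrected <- heights
  audit <- list()
  for (j in seq_len(ncol(heights))) {
    ion <- colnames(heights)[j]
    for (b in sort(unique(plan$batch))) {
      in_batch <- plan$batch == b
      qc_rows <- which(in_batch & plan$sample_type == "qc")
      usable <- qc_rows[is.finite(heights[qc_rows, j]) &
                          !fm$boundary[qc_rows, j]]
      target <- which(in_batch & plan$sample_type != "blank")
      x <- plan$injection_order[usable]
      y <- heights[usable, j]
      model <- fit_qc_drift_model(x, y, span_grid,
                                  plan$injection_order[target])
      pred <- if (!is.null(model$predicted_eval)) model$predicted_eval
              else model$predict(plan$injection_order[target])
      factor <- if (model$anchor == 0) rep(1, length(target))
                else model$anchor / pred
      corrected[target, j] <- heights[target, j] * factor
      post_qc <- corrected[qc_rows, j]
      audit[[length(audit) + 1L]] <- data.frame(
        ion_id = ion, batch = b, method = model$method, span = model$span,
        n_qc = length(usable), reason = model$reason,
        pre_rsd = rsd_percent(heights[qc_rows, j]),
        post_rsd = rsd_percent(post_qc),
        factor_min = min(factor), factor_max = max(factor),
        stringsAsFactors = FALSE)
    }
  }
  audit <- do.call(rbind, audit)
  out <- fm
  out$heights <- corrected
  out$provenance <- c(fm$provenance,
                      sprintf("loess drift correction: span grid [%s]",
                              paste(format(span_grid), collapse = ", ")))
  list(matrix = out, audit = audit)
}

#' Equalize per-ion QC medians across batches
#'
#' Per ion, each batch's values are scaled so the batch QC median equals the
#' global (all-batch) QC median. Ions whose batch QC median is zero or
#' undefined are left unscaled and flagged.
#'
#' @param fm A drift-corrected [feature_matrix()].
#' @return The batch-equalized [feature_matrix()]; unscaled ion-batches are
#'   recorded in `attr(, "unscaled")`.
#' @export
median_normalize_batches <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  plan <- fm$samples
  qc_rows <- which(plan$sample_type == "qc")
  if (!length(qc_rows)) abort("no QC samples in the plan")
  heights <- fm$heights
  unscaled <- list()
  for (j in seq_len(ncol(heights))) {
    g <- stats::median(heights[qc_rows, j], na.rm = TRUE)
    for (b in unique(plan$batch)) {
      rows_b <- which(plan$batch == b & plan$sample_type != "blank")
      qc_b <- intersect(qc_rows, which(plan$batch == b))
      m_b <- stats::median(heights[qc_b, j], na.rm = TRUE)
      if (!is.finite(m_b) || m_b == 0 || !is.finite(g)) {
        unscaled[[length(unscaled) + 1L]] <- data.frame(
          ion_id = colnames(heights)[j], batch = b, stringsAsFactors = FALSE)
        next
      }
      heights[rows_b, j] <- heights[rows_b, j] * (g / m_b)
    }
  }
  out <- fm
  out$heights <- heights
  out$provenance <- c(fm$provenance, "median normalization across batches")
  attr(out, "unscaled") <- if (length(unscaled)) do.call(rbind, unscaled)
                           else NULL
  out
}

#' Normalize a raw feature matrix (drift correction + median normalization)
#'
#' Convenience composition of [correct_batch_drift()] and
#' [median_normalize_batches()].
#'
#' @param fm Raw [feature_matrix()].
#' @param span_grid Candidate LOESS spans.
#' @return List with `matrix` and `audit`.
#' @export
normalize_features <- function(fm, span_grid = DEFAULT_SPAN_GRID) {
  step1 <- correct_batch_drift(fm, span_grid)
  list(matrix = median_normalize_batches(step1$matrix), audit = step1$audit)
}

#' k-fold cross-validated QC RSD of the normalization
#'
#' QCs are partitioned into `k` folds by injection order (rank modulo `k`).
#' For each fold the drift and median-normalization models are refit without
#' that fold's QCs, the held-out QCs are corrected by those models, and the
#' per-ion CV-RSD is the RSD of the pooled held-out corrected values. With
#' `k` equal to the number of QCs this is the leave-one-out variant.
#'
#' @param fm Raw (uncorrected) [feature_matrix()].
#' @param k Number of folds.
#' @param span_grid Candidate LOESS spans (re-selected inside each fold).
#' @param seed Unused (fold assignment is deterministic by injection order);
#'   kept so callers can thread a seed uniformly through the pipeline.
#' @return Named per-ion CV-RSD (percent).
#' @export
cv_rsd <- function(fm, k = 5L, span_grid = DEFAULT_SPAN_GRID, seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), is_count(k), k >= 2)
  plan <- fm$samples
  qc_rows <- which(plan$sample_type == "qc")
  if (length(qc_rows) < k)
    abort("only %d QC injections for k = %d folds", length(qc_rows), k)
  ord <- rank(plan$injection_order[qc_rows])
  fold <- ((ord - 1) %% k) + 1

  heights <- fm$heights
  held <- matrix(NA_real_, length(qc_rows), ncol(heights),
                 dimnames = list(plan$sample_id[qc_rows], colnames(heights)))
  for (f in seq_len(k)) {
    test_rows <- qc_rows[fold == f]
    train_rows <- qc_rows[fold != f]
    for (j in seq_len(ncol(heights))) {
      train_corr <- rep(NA_real_, length(train_rows))
      test_corr <- rep(NA_real_, length(test_rows))
      for (b in unique(plan$batch)) {
        tr_b <- train_rows[plan$batch[train_rows] == b]
        te_b <- test_rows[plan$batch[test_rows] == b]
        usable <- tr_b[is.finite(heights[tr_b, j]) & !fm$boundary[tr_b, j]]
        x <- plan$injection_order[usable]; y <- heights[usable, j]
        if (length(usable) < 2L) next
        model <- fit_qc_drift_model(x, y, span_grid,
                                    plan$injection_order[c(tr_b, te_b)])
        pred <- model$predicted_eval
        if (is.null(pred)) pred <- model$predict(
          plan$injection_order[c(tr_b, te_b)])
        factor <- if (model$anchor == 0) rep(1, length(pred))
                  else model$anchor / pred
        corr <- heights[c(tr_b, te_b), j] * factor
        train_corr[match(tr_b, train_rows)] <- corr[seq_along(tr_b)]
        test_corr[match(te_b, test_rows)] <- corr[length(tr_b) +
                                                    seq_along(te_b)]
      }
      # median normalization from the training QCs only
      g <- stats::median(train_corr, na.rm = TRUE)
      for (b in unique(plan$batch)) {
        te_b <- which(plan$batch[test_rows] == b)
        tr_b <- which(plan$batch[train_rows] == b)
        if (!length(te_b)) next
        m_b <- stats::median(train_corr[tr_b], na.rm = TRUE)
        scale_b <- if (is.finite(m_b) && m_b != 0 && is.finite(g))
          g / m_b else 1
        held[match(test_rows[te_b], qc_rows), j] <- test_corr[te_b] * scale_b
      }
    }
  }
  apply(held, 2L, rsd_percent)
}
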