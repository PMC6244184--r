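# Adduct / dual-polarity deduplication and RSD-based feature filtering.
#
# One lipid can be detected as several adducts in both ionization modes. To
# keep one measurement per lipid, the adduct with the lowest QC RSD wins
# within each mode, then the lower-RSD mode wins across modes; for dual-mode
# lipids the Spearman concordance of the two candidates is reported (never
# used for removal). Ions above the QC RSD threshold and all internal
# standards are dropped from the final matrix.

#' Relative standard deviation, percent
#'
#' `100 x sample standard deviation (n - 1 denominator) / mean`.
#'
#' @param values At least two finite values.
#' @return RSD in percent; `NA` with a warning when the mean is zero
#'   (undefined).
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    abort("RSD requires at least 2 finite values (got %d)", length(values))
  m <- mean(values)
  if (m == 0) {
    warning("RSD undefined: mean is zero", call. = FALSE)
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Per-ion QC RSD of a feature matrix
#'
#' @param fm A [feature_matrix()].
#' @return Named numeric vector (percent); `NA` where undefined.
#' @export
qc_rsd <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  qc_rows <- fm$samples$sample_type == "qc"
  if (!any(qc_rows)) abort("no QC samples in the plan")
  apply(fm$heights[qc_rows, , drop = FALSE], 2L, rsd_percent)
}

# Deterministic candidate ordering for RSD ties: positive mode first, then
# adduct label lexicographically, then ion_id. Locale-independent.
tie_order <- function(ions) {
  order(ions$mode != "positive",
        rank(ions$adduct, ties.method = "min"),
        rank(ions$ion_id, ties.method = "min"))
}

#' Select one adduct per (lipid, mode) by lowest QC RSD
#'
#' Members with an undefined RSD lose to any member with a defined one;
#' lipids whose members are all undefined in a mode are dropped from that
#' mode and logged. Exact ties resolve deterministically (positive mode
#' first, then adduct label, then ion id).
#'
#' @param db An [ion_database()]; internal standards are not candidates.
#' @param qc_rsd_values Named per-ion QC RSD (percent), e.g. from
#'   [qc_rsd()].
#' @return List with `selected` (data frame: lipid_id, mode, ion_id,
#'   adduct, qc_rsd) and `dropped` (lipid-modes with no defined RSD).
#' @export
select_adduct_within_mode <- function(db, qc_rsd_values) {
  cand <- as.data.frame(db)[!db$is_internal_standard, , drop = FALSE]
  missing_ions <- setdiff(cand$ion_id, names(qc_rsd_values))
  if (length(missing_ions))
    abort("no QC RSD for ion(s): %s", paste(missing_ions, collapse = ", "))
  cand$qc_rsd <- unname(qc_rsd_values[cand$ion_id])
  cand <- cand[tie_order(cand), , drop = FALSE]

  selected <- list(); dropped <- list()
  for (key in unique(paste(cand$lipid_id, cand$mode, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    grp <- cand[cand$lipid_id == parts[1] & cand$mode == parts[2], ,
                drop = FALSE]
    ok <- is.finite(grp$qc_rsd)
    if (!any(ok)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        lipid_id = parts[1], mode = parts[2],
        reason = "all adducts have undefined QC RSD",
        stringsAsFactors = FALSE)
      next
    }
    grp <- grp[ok, , drop = FALSE]
    win <- grp[which.min(grp$qc_rsd), , drop = FALSE]  # first min = tie rule
    selected[[length(selected) + 1L]] <- data.frame(
      lipid_id = win$lipid_id, mode = win$mode, ion_id = win$ion_id,
      adduct = win$adduct, qc_rsd = win$qc_rsd, stringsAsFactors = FALSE)
  }
  list(
    selected = if (length(selected)) do.call(rbind, selected)
               else data.frame(lipid_id = character(), mode = character(),
                               ion_id = character(), adduct = character(),
                               qc_rsd = numeric()),
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL)
}

#' Deduplicate dual-mode lipids and report cross-mode concordance
#'
#' For lipids detected in both modes, the per-mode winner with the lower QC
#' RSD enters the final matrix; the Spearman correlation between the two
#' candidates' peak heights across all non-blank samples is reported with a
#' `concordant` flag at `rho >= 0.80` (descriptive only, never a removal
#' criterion).
#'
#' @param selection Result of [select_adduct_within_mode()].
#' @param fm The (normalized) [feature_matrix()] providing peak heights.
#' @return Data frame, one row per lipid: `lipid_id`, `ion_id`, `mode`,
#'   `adduct`, `qc_rsd`, `n_modes`, `spearman_rho`, `concordant`.
#' @export
dedup_across_modes <- function(selection, fm) {
  sel <- selection$selected
  stopifnot(inherits(fm, "feature_matrix"))
  nonblank <- fm$samples$sample_type != "blank"
  out <- list()
  for (lid in unique(sel$lipid_id)) {
    grp <- sel[sel$lipid_id == lid, , drop = FALSE]
    grp <- grp[order(grp$mode != "positive"), , drop = FALSE]
    rho <- NA_real_
    if (nrow(grp) == 2L) {
      a <- fm$heights[nonblank, grp$ion_id[1]]
      b <- fm$heights[nonblank, grp$ion_id[2]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) >= 3L)
        rho <- stats::cor(a[ok], b[ok], method = "spearman")
      win <- grp[which.min(grp$qc_rsd), , drop = FALSE]
    } else {
      win <- grp[1L, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- data.frame(
      lipid_id = lid, ion_id = win$ion_id, mode = win$mode,
      adduct = win$adduct, qc_rsd = win$qc_rsd, n_modes = nrow(grp),
      spearman_rho = rho,
      concordant = if (is.na(rho)) NA else rho >= 0.80,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Filter ions by QC RSD and drop internal standards
#'
#' Ions with QC RSD strictly greater than `threshold` are removed (a value
#' exactly at the threshold is retained); internal standards are always
#' removed (they are calibration devices, not analytes); ions with an
#' undefined QC RSD are removed as unquantifiable. The operation is
#' idempotent.
#'
#' @param fm A [feature_matrix()].
#' @param threshold QC RSD threshold, percent.
#' @param qc_rsd_values Optional precomputed per-ion QC RSD.
#' @return List with `matrix` (filtered [feature_matrix()]) and `removed`
#'   (log of dropped ions with their RSD and reason).
#' @export
apply_rsd_filter <- function(fm, threshold = 25, qc_rsd_values = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(qc_rsd_values)) qc_rsd_values <- qc_rsd(fm)
  r <- unname(qc_rsd_values[colnames(fm$heights)])
  is_is <- fm$ions$is_internal_standard
  reason <- rep(NA_character_, ncol(fm$heights))
  reason[!is.finite(r)] <- "undefined QC RSD"
  reason[is.finite(r) & r > threshold] <-
    sprintf("QC RSD above %.4g%%", threshold)
  reason[is_is] <- "internal standard"
  drop <- !is.na(reason)
  removed <- data.frame(ion_id = colnames(fm$heights)[drop],
                        qc_rsd = r[drop], reason = reason[drop],
                        stringsAsFactors = FALSE)
  list(matrix = subset_ions(fm, !drop,
                            sprintf("RSD filter: > %.4g%% removed",
                                    threshold)),
       removed = removed)
}

# Column subset of a feature matrix, preserving companions and annotations.
subset_ions <- function(fm, keep, note) {
  out <- fm
  for (field in c("heights", "apex_rt", "snr", "boundary"))
    if (!is.null(out[[field]]))
      out[[field]] <- out[[field]][, keep, drop = FALSE]
  out$ions <- fm$ions[keep, , drop = FALSE]
  rownames(out$ions) <- NULL
  out$provenance <- c(fm$provenance, note)
  out
}

#' Build the final one-column-per-lipid matrix
#'
#' Applies the dedup selection and the RSD filter to a normalized feature
#' matrix; columns of the result are named by `lipid_id`.
#'
#' @param fm Normalized [feature_matrix()].
#' @param dedup Result of [dedup_across_modes()].
#' @param threshold QC RSD filter threshold, percent.
#' @return List with `matrix` (final [feature_matrix()], columns = one ion
#'   per lipid), `removed` (filter log) and `lipid_ids` (column lipid ids).
#' @export
finalize_lipid_matrix <- function(fm, dedup, threshold = 25) {
  keep <- colnames(fm$heights) %in% dedup$ion_id
  selected <- subset_ions(fm, keep, "adduct/mode deduplication")
  filt <- apply_rsd_filter(selected, threshold)
  final <- filt$matrix
  list(matrix = final, removed = filt$removed,
       lipid_ids = final$ions$lipid_id)
}

#' Build the data dictionary for a final matrix
#'
#' One row per retained ion: lipid name, ionization mode, adduct, precursor
#' m/z, expected retention time, InChIKey and known/unknown status.
#'
#' @param fm Final [feature_matrix()].
#' @param db The full [ion_database()].
#' @return Data frame dictionary.
#' @export
build_data_dictionary <- function(fm, db) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- match(fm$ions$ion_id, db$ion_id)
  if (anyNA(idx))
    abort("ion(s) absent from the database: %s",
          paste(fm$ions$ion_id[is.na(idx)], collapse = ", "))
  data.frame(
    lipid_id = db$lipid_id[idx], name = db$name[idx], mode = db$mode[idx],
    adduct = db$adduct[idx], mz = db$mz[idx],
    expected_rt = db$expected_rt[idx], inchikey = db$inchikey[idx],
    is_known = db$is_known[idx], stringsAsFactors = FALSE)
}

#' Write the final lipid matrix and dictionary to CSV
#'
#' The matrix file has the sample identifier first and one column per lipid
#' id; the dictionary mirrors [build_data_dictionary()].
#'
#' @param final Result of [finalize_lipid_matrix()].
#' @param dictionary Result of [build_data_dictionary()].
#' @param prefix Output path prefix.
#' @return Invisibly, the matrix path.
#' @export
write_final_matrix <- function(final, dictionary, prefix) {
  fm <- final$matrix
  df <- data.frame(sample_id = rownames(fm$heights),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(fm$heights)))
    df[[fm$ions$lipid_id[j]]] <- format_full(fm$heights[, j])
  df[df == "NA"] <- ""
  path <- paste0(prefix, "_final_matrix.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(dictionary, paste0(prefix, "_dictionary.csv"),
                   row.names = FALSE)
  invisible(path)
}
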