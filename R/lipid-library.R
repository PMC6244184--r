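# Target-ion database model and monoisotopic adduct mass arithmetic.
#
# The database drives targeted EIC extraction: one row per (lipid, mode,
# adduct) with the m/z to extract and the expected retention time at which
# the apex is searched. Internal standards are flagged rows used for
# retention-time recalibration; "known unknowns" carry m/z and RT only.

# IUPAC monoisotopic atomic masses (Da). Hard-coded in one table so that
# m/z arithmetic is bit-exact across platforms.
MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809
)

ELECTRON_MASS <- 0.000548579909

# Supported singly charged adducts: mass delta relative to the neutral
# monoisotopic mass, electron mass included (subtracted for cations, added
# for anions).
ADDUCT_TABLE <- local({
  m <- MONOISOTOPIC_MASS
  data.frame(
    adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+OAc]-"),
    polarity = c("positive", "positive", "positive", "negative", "negative"),
    delta = c(
      m[["H"]] - ELECTRON_MASS,
      m[["N"]] + 4 * m[["H"]] - ELECTRON_MASS,
      m[["Na"]] - ELECTRON_MASS,
      -m[["H"]] + ELECTRON_MASS,
      2 * m[["C"]] + 3 * m[["H"]] + 2 * m[["O"]] + ELECTRON_MASS
    ),
    stringsAsFactors = FALSE
  )
})

#' Supported adduct labels
#'
#' @return Character vector of the singly charged adducts understood by
#'   [adduct_mz()]: `[M+H]+`, `[M+NH4]+`, `[M+Na]+`, `[M-H]-`, `[M+OAc]-`.
#'   The typographic minus (`−`) is accepted as a synonym of `-`.
#' @export
supported_adducts <- function() ADDUCT_TABLE$adduct

normalize_adduct <- function(adduct) {
  gsub("−", "-", adduct, fixed = TRUE)
}

#' Build an elemental formula
#'
#' Either from a string such as `"C61H102O6"` or from named counts.
#'
#' @param x Formula string, or a named numeric vector of element counts.
#' @return An `elemental_formula`: named integer vector of positive counts.
#' @examples
#' elemental_formula("H2O")
#' elemental_formula(c(C = 5, H = 4, N = 4))
#' @export
elemental_formula <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!nzchar(x)) abort("empty formula")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    parts <- regmatches(x, list(m))[[1]]
    if (sum(nchar(parts)) != nchar(x)) abort("cannot parse formula '%s'", x)
    el <- sub("[0-9]*$", "", parts)
    n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
    counts <- tapply(n, el, sum)
    x <- stats::setNames(as.numeric(counts), names(counts))
  }
  if (!is.numeric(x) || is.null(names(x)) || length(x) == 0L)
    abort("empty formula")
  unknown <- setdiff(names(x), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    abort("unknown element symbol(s): %s", paste(unknown, collapse = ", "))
  if (any(x <= 0 | x != floor(x)))
    abort("element counts must be positive integers")
  structure(stats::setNames(as.integer(x), names(x)),
            class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  ord <- c("C", "H", intersect(sort(names(x)), setdiff(names(x), c("C", "H"))))
  ord <- ord[ord %in% names(x)]
  paste0(ord, ifelse(unclass(x)[ord] > 1, unclass(x)[ord], ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula An [elemental_formula()] (or string / named counts coercible
#'   to one).
#' @return Mass in Da (sum of count times monoisotopic atomic mass).
#' @examples
#' monoisotopic_mass("H2O")   # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  sum(unclass(f) * MONOISOTOPIC_MASS[names(f)])
}

as_formula <- function(formula) {
  if (inherits(formula, "elemental_formula")) formula
  else elemental_formula(formula)
}

#' Theoretical m/z of a singly charged adduct
#'
#' Neutral monoisotopic mass plus the adduct mass delta, with the electron
#' mass subtracted for cations and added for anions. Full precision is kept
#' internally; use `digits` for the conventional 4-decimal display rounding
#' (half-even, as in [round()]).
#'
#' @param formula Neutral elemental formula.
#' @param adduct One of [supported_adducts()].
#' @param digits Optional rounding digits (`NA` = full precision).
#' @return m/z in Th.
#' @examples
#' adduct_mz(tg_formula(58, 8), "[M+NH4]+", digits = 4)  # 948.8015
#' adduct_mz("C5H4N4", "[M+H]+", digits = 4)             # 121.0509
#' @export
adduct_mz <- function(formula, adduct, digits = NA) {
  adduct <- normalize_adduct(adduct)
  i <- match(adduct, ADDUCT_TABLE$adduct)
  if (is.na(i))
    abort("unsupported adduct '%s' (supported: %s)", adduct,
          paste(ADDUCT_TABLE$adduct, collapse = ", "))
  mz <- monoisotopic_mass(formula) + ADDUCT_TABLE$delta[i]
  if (is.na(digits)) mz else round(mz, digits)
}

#' Elemental formula of a triacylglycerol from its shorthand
#'
#' Maps the `TG(n:d)` shorthand (n total acyl carbons, d total double bonds)
#' to the neutral formula C(n+3) H(2n+2-2d) O6.
#'
#' @param total_acyl_carbons Total carbons across the three acyl chains.
#' @param double_bonds Total number of C=C double bonds.
#' @return An [elemental_formula()].
#' @examples
#' tg_formula(48, 0)  # tripalmitin, C51H98O6
#' @export
tg_formula <- function(total_acyl_carbons, double_bonds) {
  n <- total_acyl_carbons; d <- double_bonds
  if (!is_count(n) || n < 6) abort("need at least 6 total acyl carbons")
  if (!is_count(d)) abort("double_bonds must be a nonnegative integer")
  h <- 2 * n + 2 - 2 * d
  if (h <= 0)
    abort("impossible formula: %d double bonds leave %d hydrogens", d, h)
  elemental_formula(c(C = n + 3, H = h, O = 6))
}

ION_DB_COLUMNS <- c("ion_id", "lipid_id", "name", "mode", "adduct", "mz",
                    "expected_rt", "inchikey", "is_internal_standard",
                    "is_known")

#' Construct a validated target-ion database
#'
#' @param ions Data frame with columns `ion_id`, `lipid_id`, `name`, `mode`
#'   (`"positive"`/`"negative"`), `adduct`, `mz` (Th), `expected_rt`
#'   (minutes), `inchikey` (empty string for known unknowns),
#'   `is_internal_standard`, `is_known` (logicals).
#' @param min_internal_standards Minimum internal standards required per
#'   present mode (at least 3 are needed for the quadratic RT recalibration).
#' @return An `ion_database` (data frame subclass).
#' @export
ion_database <- function(ions, min_internal_standards = 3L) {
  missing_cols <- setdiff(ION_DB_COLUMNS, names(ions))
  if (length(missing_cols))
    abort("ion table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  ions <- as.data.frame(ions)[ION_DB_COLUMNS]
  for (col in c("ion_id", "lipid_id", "name", "mode", "adduct", "inchikey"))
    ions[[col]] <- as.character(ions[[col]])
  ions$inchikey[is.na(ions$inchikey)] <- ""
  ions$mz <- as.numeric(ions$mz)
  ions$expected_rt <- as.numeric(ions$expected_rt)
  ions$is_internal_standard <- as.logical(ions$is_internal_standard)
  ions$is_known <- as.logical(ions$is_known)

  problems <- validate_ion_rows(ions)
  if (nrow(problems))
    abort("invalid ion database (%d problem%s):\n%s", nrow(problems),
          if (nrow(problems) > 1) "s" else "",
          paste(sprintf("  row %s [%s]: %s", problems$row, problems$key,
                        problems$problem), collapse = "\n"))

  for (mode in unique(ions$mode)) {
    n_is <- sum(ions$is_internal_standard[ions$mode == mode])
    if (n_is < min_internal_standards)
      abort(paste0("mode '%s' has %d internal standard(s); at least %d are ",
                   "required for quadratic RT recalibration"),
            mode, n_is, min_internal_standards)
  }
  rownames(ions) <- NULL
  structure(ions, class = c("ion_database", "data.frame"))
}

# Per-row invariant report: data.frame(row, key, problem), empty when valid.
validate_ion_rows <- function(ions) {
  out <- list()
  note <- function(rows, problem) {
    if (length(rows))
      out[[length(out) + 1L]] <<- data.frame(
        row = rows,
        key = paste(ions$mode[rows], ions$adduct[rows], ions$lipid_id[rows],
                    sep = "/"),
        problem = problem, stringsAsFactors = FALSE)
  }
  note(which(!ions$mode %in% c("positive", "negative")),
       "mode must be 'positive' or 'negative'")
  note(which(!is.finite(ions$mz) | ions$mz <= 0), "mz must be > 0")
  note(which(!is.finite(ions$expected_rt) | ions$expected_rt <= 0),
       "expected_rt must be > 0")
  note(which(duplicated(ions$ion_id) | duplicated(ions$ion_id, fromLast = TRUE)),
       "duplicate ion_id")
  key <- paste(ions$mode, ions$adduct, ions$lipid_id, sep = "/")
  note(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
       "duplicate (mode, adduct, lipid_id)")
  note(which(ions$is_internal_standard & !ions$is_known),
       "internal standards must be flagged as known")
  note(which(!ions$is_known & nzchar(ions$inchikey)),
       "known unknowns must have an empty inchikey")
  if (!length(out))
    return(data.frame(row = integer(), key = character(),
                      problem = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' @export
print.ion_database <- function(x, ...) {
  cat(sprintf("<ion_database> %d target ions (%d lipids)\n",
              nrow(x), length(unique(x$lipid_id))))
  for (m in sort(unique(x$mode), decreasing = TRUE))
    cat(sprintf("  %s: %d ions, %d internal standards, %d known unknowns\n",
                m, sum(x$mode == m),
                sum(x$is_internal_standard & x$mode == m),
                sum(!x$is_known & x$mode == m)))
  invisible(x)
}

#' Internal-standard subset of a database
#' @param db An [ion_database()].
#' @param mode Optional mode filter.
#' @return The internal-standard rows.
#' @export
internal_standards <- function(db, mode = NULL) {
  keep <- db$is_internal_standard
  if (!is.null(mode)) keep <- keep & db$mode == mode
  db[keep, , drop = FALSE]
}

#' Load a target-ion database from CSV
#'
#' Expected header: `ion_id, lipid_id, name, mode, adduct, mz, expected_rt,
#' inchikey, is_internal_standard, is_known`. The ionization mode is encoded
#' with configurable tokens (default `ESI+` / `ESI-`).
#'
#' @param path CSV file path.
#' @param mode_labels Named character vector mapping the internal mode names
#'   to the file tokens.
#' @param min_internal_standards Passed to [ion_database()].
#' @return An [ion_database()].
#' @export
load_ion_database <- function(path,
                              mode_labels = c(positive = "ESI+",
                                              negative = "ESI-"),
                              min_internal_standards = 3L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(ION_DB_COLUMNS, names(tab))
  if (length(missing_cols))
    abort("database file %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  lookup <- stats::setNames(names(mode_labels),
                            normalize_adduct(mode_labels))
  tok <- normalize_adduct(tab$mode)
  if (any(!tok %in% names(lookup)))
    abort("unrecognized mode token(s): %s",
          paste(unique(tok[!tok %in% names(lookup)]), collapse = ", "))
  tab$mode <- unname(lookup[tok])
  tab$adduct <- normalize_adduct(tab$adduct)
  tab$mz <- as.numeric(tab$mz)
  tab$expected_rt <- as.numeric(tab$expected_rt)
  tab$is_internal_standard <- tab$is_internal_standard %in% c("TRUE", "true", "1")
  tab$is_known <- tab$is_known %in% c("TRUE", "true", "1")
  ion_database(tab, min_internal_standards = min_internal_standards)
}

#' Write a target-ion database to CSV
#'
#' Inverse of [load_ion_database()]; the round trip preserves every field
#' (m/z and RT written at full precision).
#'
#' @param db An [ion_database()].
#' @param path Output CSV path.
#' @param mode_labels Mode tokens used in the file.
#' @return `path`, invisibly.
#' @export
write_ion_database <- function(db, path,
                               mode_labels = c(positive = "ESI+",
                                               negative = "ESI-")) {
  out <- as.data.frame(db)
  out$mode <- unname(mode_labels[out$mode])
  out$mz <- format_full(out$mz)
  out$expected_rt <- format_full(out$expected_rt)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Full-precision decimal text (round-trips doubles exactly).
format_full <- function(x) trimws(formatC(x, digits = 17, format = "g"))
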