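# RSD computation, adduct selection, cross-mode dedup, RSD filter,
# data dictionary.

test_that("rsd follows the n-1 sample definition in percent", {
  expect_identical(rsd(c(1, 2, 3)), 50)  # sd 1, mean 2
  expect_identical(rsd(rep(4, 5)), 0)
  expect_error(rsd(3), "at least 2")
  expect_warning(r0 <- rsd(c(-1, 1)), "mean is zero")
  expect_true(is.na(r0))
})

make_group_db <- function(spec_rows) {
  # spec_rows: data.frame(lipid_id, mode, adduct)
  spec_rows$ion_id <- sprintf("ion%02d", seq_len(nrow(spec_rows)))
  spec_rows$name <- spec_rows$lipid_id
  spec_rows$mz <- 500 + seq_len(nrow(spec_rows))
  spec_rows$expected_rt <- 5
  spec_rows$inchikey <- "K"
  spec_rows$is_internal_standard <- FALSE
  spec_rows$is_known <- TRUE
  ion_database(spec_rows, min_internal_standards = 0L)
}

test_that("lowest QC RSD picks the adduct, undefined RSD loses", {
  db <- make_group_db(data.frame(
    lipid_id = c("L1", "L1", "L2", "L2"),
    mode = "positive",
    adduct = c("[M+H]+", "[M+Na]+", "[M+H]+", "[M+NH4]+"),
    stringsAsFactors = FALSE))
  r <- c(ion01 = 12, ion02 = 8, ion03 = NA, ion04 = 30)
  sel <- select_adduct_within_mode(db, r)
  expect_identical(sel$selected$ion_id[sel$selected$lipid_id == "L1"],
                   "ion02")
  expect_identical(sel$selected$ion_id[sel$selected$lipid_id == "L2"],
                   "ion04")

  # all undefined: dropped and logged
  sel2 <- select_adduct_within_mode(db, c(ion01 = 1, ion02 = 2,
                                          ion03 = NA, ion04 = NA))
  expect_identical(sel2$dropped$lipid_id, "L2")
})

test_that("exact RSD ties resolve deterministically by adduct label", {
  db <- make_group_db(data.frame(
    lipid_id = "L1", mode = "positive",
    adduct = c("[M+Na]+", "[M+H]+"), stringsAsFactors = FALSE))
  r <- c(ion01 = 10, ion02 = 10)
  s1 <- select_adduct_within_mode(db, r)$selected$ion_id
  s2 <- select_adduct_within_mode(db, r)$selected$ion_id
  expect_identical(s1, s2)
  expect_identical(s1, "ion02")  # "[M+H]+" sorts before "[M+Na]+"
})

test_that("selection equals brute-force argmin on random groups", {
  set.seed(101)
  adducts_pos <- c("[M+H]+", "[M+NH4]+", "[M+Na]+")
  for (g in 1:100) {
    k <- sample(2:3, 1)
    db <- make_group_db(data.frame(
      lipid_id = "L", mode = "positive",
      adduct = sample(adducts_pos, k), stringsAsFactors = FALSE))
    r <- stats::setNames(round(stats::runif(k, 1, 40), 3), db$ion_id)
    sel <- select_adduct_within_mode(db, r)$selected
    expect_identical(sel$ion_id, names(r)[which.min(r)])
  }
})

dual_mode_fixture <- function(rho_noise = 0.1, n = 40, seed = 7) {
  set.seed(seed)
  db <- make_group_db(data.frame(
    lipid_id = "L1", mode = c("positive", "negative"),
    adduct = c("[M+H]+", "[M-H]-"), stringsAsFactors = FALSE))
  plan <- build_injection_sequence(n, 1, n_duplicate_pairs = 0, seed = seed)
  conc <- exp(stats::rnorm(nrow(plan), log(1e5), 0.5))
  h <- cbind(conc * exp(stats::rnorm(nrow(plan), 0, rho_noise)),
             2 * conc * exp(stats::rnorm(nrow(plan), 0, rho_noise)))
  dimnames(h) <- list(plan$sample_id, db$ion_id)
  fm <- feature_matrix(h, plan, db)
  list(db = db, fm = fm)
}

test_that("dual-mode lipids keep the lower-RSD mode and report concordance", {
  fx <- dual_mode_fixture()
  rsds <- qc_rsd(fx$fm)
  sel <- select_adduct_within_mode(fx$db, rsds)
  dd <- dedup_across_modes(sel, fx$fm)
  expect_identical(nrow(dd), 1L)
  expect_identical(dd$ion_id, sel$selected$ion_id[
    which.min(sel$selected$qc_rsd)])
  expect_identical(dd$n_modes, 2L)
  expect_true(dd$concordant)  # shared concentration, mild noise
  expect_gte(dd$spearman_rho, 0.80)
})

test_that("single-mode lipids pass through with an empty rho", {
  db <- make_group_db(data.frame(lipid_id = "L9", mode = "positive",
                                 adduct = "[M+H]+",
                                 stringsAsFactors = FALSE))
  plan <- build_injection_sequence(20, 1, n_duplicate_pairs = 0, seed = 2)
  h <- matrix(stats::rlnorm(nrow(plan), log(1e4), 0.2), ncol = 1,
              dimnames = list(plan$sample_id, db$ion_id))
  fm <- feature_matrix(h, plan, db)
  dd <- dedup_across_modes(select_adduct_within_mode(db, qc_rsd(fm)), fm)
  expect_identical(dd$ion_id, "ion01")
  expect_true(is.na(dd$spearman_rho))
})

test_that("spearman concordance equals a rank-then-correlate oracle", {
  for (s in 1:20) {
    fx <- dual_mode_fixture(rho_noise = stats::runif(1, 0.05, 0.6),
                            n = 30, seed = 200 + s)
    dd <- dedup_across_modes(
      select_adduct_within_mode(fx$db, qc_rsd(fx$fm)), fx$fm)
    nb <- fx$fm$samples$sample_type != "blank"
    a <- fx$fm$heights[nb, 1]; b <- fx$fm$heights[nb, 2]
    oracle <- stats::cor(rank(a), rank(b))
    expect_equal(dd$spearman_rho, oracle, tolerance = 1e-12)
  }
})

test_that("RSD filter is strict at the threshold and drops standards", {
  db <- tiny_db(n_lipids = 4, seed = 12)
  plan <- build_injection_sequence(30, 1, n_duplicate_pairs = 0, seed = 3)
  qc <- plan$sample_type == "qc"
  h <- matrix(1000, nrow(plan), nrow(db),
              dimnames = list(plan$sample_id, db$ion_id))
  # engineer exact QC RSDs on the first two analyte ions
  analytes <- which(!db$is_internal_standard)
  qc_vals <- function(target_rsd) {
    v <- c(1000 - 10, 1000, 1000 + 10)
    m <- mean(v); s <- stats::sd(v)
    (v - m) * (target_rsd / 100 * m / s) + m
  }
  h[qc, analytes[1]] <- qc_vals(25.0)   # exactly at threshold: retained
  h[qc, analytes[2]] <- qc_vals(25.01)  # just above: removed
  fm <- feature_matrix(h, plan, db)
  res <- apply_rsd_filter(fm, threshold = 25)

  kept <- res$matrix$ions$ion_id
  expect_true(db$ion_id[analytes[1]] %in% kept)
  expect_false(db$ion_id[analytes[2]] %in% kept)
  expect_no_internal_standards(res$matrix)
  expect_identical(
    sort(res$removed$ion_id),
    sort(c(db$ion_id[db$is_internal_standard], db$ion_id[analytes[2]])))

  # idempotence and recount oracle
  res2 <- apply_rsd_filter(res$matrix, threshold = 25)
  expect_identical(res2$matrix$heights, res$matrix$heights)
  r <- qc_rsd(fm)
  brute_kept <- sum(!db$is_internal_standard & is.finite(r) & r <= 25)
  expect_identical(ncol(res$matrix$heights), brute_kept)
})

test_that("the data dictionary is a bijection over final ions", {
  run <- small_run(n_study = 60, n_batches = 2, n_lipids = 8, seed = 19)
  fm <- extract_features(run$eics)
  norm <- normalize_features(fm)$matrix
  filt <- run_filter(norm, run$db, pipeline_config())
  dict <- filt$dictionary
  expect_identical(nrow(dict), ncol(filt$matrix$heights))
  expect_identical(dict$lipid_id, filt$matrix$ions$lipid_id)
  expect_identical(sum(dict$is_known),
                   sum(run$db$is_known[match(filt$matrix$ions$ion_id,
                                             run$db$ion_id)]))
  # round trip
  d <- withr::local_tempdir()
  write_final_matrix(list(matrix = filt$matrix), dict,
                     file.path(d, "out"))
  back <- utils::read.csv(file.path(d, "out_dictionary.csv"),
                          stringsAsFactors = FALSE)
  expect_identical(back$lipid_id, dict$lipid_id)
  expect_equal(back$mz, dict$mz, tolerance = 1e-9)

  # orphan ion errors
  expect_error(build_data_dictionary(filt$matrix, tiny_db(2, seed = 1)),
               "absent from the database")
})

test_that("after dedup each lipid appears at most once, with optimal RSD", {
  run <- small_run(n_study = 100, n_batches = 2, n_lipids = 10, seed = 29)
  fm <- extract_features(run$eics)
  norm <- normalize_features(fm)$matrix
  rsds <- qc_rsd(norm)
  sel <- select_adduct_within_mode(run$db, rsds)
  dd <- dedup_across_modes(sel, norm)
  expect_false(any(duplicated(dd$lipid_id)))
  # winner optimality against every database member of the lipid
  for (i in seq_len(nrow(dd))) {
    members <- run$db$ion_id[run$db$lipid_id == dd$lipid_id[i] &
                               !run$db$is_internal_standard]
    expect_lte(dd$qc_rsd[i], min(rsds[members], na.rm = TRUE) + 1e-12)
  }
  final <- finalize_lipid_matrix(norm, dd, threshold = 25)
  expect_false(any(duplicated(final$matrix$ions$lipid_id)))
  expect_no_internal_standards(final$matrix)
})
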