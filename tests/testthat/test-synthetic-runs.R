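# Injection-sequence design and the synthetic EIC generator.

test_that("injection design arithmetic: QCs and blanks per block", {
  plan <- build_injection_sequence(100, 4, 10, 10, n_duplicate_pairs = 0,
                                   seed = 1)
  expect_identical(sum(plan$sample_type == "qc"), 10L)
  expect_identical(sum(plan$sample_type == "blank"), 10L)
  expect_identical(sum(plan$sample_type == "study"), 100L)
  expect_true(all(diff(plan$injection_order) == 1))
  # batches contiguous in injection order
  expect_true(all(diff(plan$batch) >= 0))
})

test_that("large-cohort design: QC count and in-batch preceding blocks", {
  plan <- build_injection_sequence(806, 4, 10, 10, n_duplicate_pairs = 20,
                                   seed = 2)
  expect_identical(sum(plan$sample_type == "qc"),
                   as.integer(ceiling(806 / 10)))
  # brute-force: every non-trailing QC is preceded by exactly qc_interval
  # study injections within its batch
  for (b in unique(plan$batch)) {
    pb <- plan[plan$batch == b, ]
    n_study_seen <- 0L
    for (i in seq_len(nrow(pb))) {
      if (pb$sample_type[i] == "study") n_study_seen <- n_study_seen + 1L
      if (pb$sample_type[i] == "qc") {
        expect_true(n_study_seen == 10L || i == nrow(pb) ||
                      all(pb$sample_type[i:nrow(pb)] != "study"))
        n_study_seen <- 0L
      }
    }
  }
})

test_that("plans are reproducible from the seed and vary across seeds", {
  p1 <- build_injection_sequence(60, 2, seed = 5)
  p2 <- build_injection_sequence(60, 2, seed = 5)
  p3 <- build_injection_sequence(60, 2, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1$sample_id, p3$sample_id))
  expect_error(build_injection_sequence(10, 1, n_duplicate_pairs = 6),
               "cannot exceed")
})

test_that("duplicate pairs reference exactly one earlier or later study sample", {
  plan <- build_injection_sequence(120, 3, n_duplicate_pairs = 15, seed = 3)
  dup <- plan[!is.na(plan$duplicate_of), ]
  expect_identical(nrow(dup), 15L)
  expect_true(all(dup$duplicate_of %in%
                    plan$sample_id[plan$sample_type == "study"]))
  expect_false(any(duplicated(dup$duplicate_of)))
})

test_that("ground truth: QC pool fixed, duplicates share levels, adduct ratios constant", {
  run <- small_run(n_study = 60, n_batches = 2, n_duplicate_pairs = 5,
                   noise_cv = 0, drift_amplitude = 0)
  truth <- run$truth; plan <- run$plan; db <- run$db
  qc_ids <- plan$sample_id[plan$sample_type == "qc"]
  expect_true(all(apply(truth$concentrations[, qc_ids, drop = FALSE], 1,
                        function(x) diff(range(x)) == 0)))
  dup <- plan[!is.na(plan$duplicate_of), ]
  expect_identical(unname(truth$concentrations[, dup$sample_id]),
                   unname(truth$concentrations[, dup$duplicate_of]))

  # two adducts of one lipid, no noise: intensity ratio across samples is
  # the stored response-factor ratio
  counts <- table(paste(db$lipid_id, db$mode))
  multi <- names(counts)[counts >= 2][1]
  skip_if(is.na(multi), "no multi-adduct lipid drawn")
  pair <- db$ion_id[paste(db$lipid_id, db$mode) == multi][1:2]
  h <- run$eics$true_heights
  nb <- plan$sample_type != "blank"
  ratio <- h[nb, pair[1]] / h[nb, pair[2]]
  expect_equal(ratio, rep(truth$response[pair[1]] / truth$response[pair[2]],
                          sum(nb)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("no-noise, no-baseline EICs place the apex at the distorted RT", {
  run <- small_run(n_study = 20, n_batches = 1, n_lipids = 4,
                   noise_cv = 0, baseline_level = 0, baseline_noise = 0,
                   carryover_fraction = 0)
  eics <- run$eics
  step <- run$params$rt_grid_step
  sid <- run$plan$sample_id[run$plan$sample_type == "study"][1]
  for (j in seq_len(nrow(run$db))) {
    tr <- eic_trace(eics, sid, run$db$ion_id[j])
    i <- which.max(tr$intensity)
    expect_lte(abs(tr$rt[i] - eics$true_apex_rt[sid, j]), step / 2)
    expect_gte(max(tr$intensity),
               eics$true_heights[sid, j] * exp(-step^2 / (8 * 0.02^2)) - 1e-9)
    expect_lte(max(tr$intensity), eics$true_heights[sid, j] + 1e-9)
  }
})

test_that("blanks carry only baseline without carryover, and scale with it", {
  run0 <- small_run(n_study = 30, n_batches = 1, n_lipids = 4,
                    carryover_fraction = 0)
  blanks <- run0$plan$sample_id[run0$plan$sample_type == "blank"]
  cap <- run0$params$baseline_level + run0$params$baseline_noise
  for (b in blanks)
    expect_lte(max(run0$eics$intensity[[b]]), cap + 1e-9)

  run1 <- small_run(n_study = 30, n_batches = 1, n_lipids = 4,
                    carryover_fraction = 0.1)
  b1 <- blanks[1]
  expect_gt(max(run1$eics$intensity[[b1]]), cap)
})

test_that("out-of-span RT distortion is rejected naming the ion", {
  db <- tiny_db(n_lipids = 3, seed = 2)
  plan <- build_injection_sequence(10, 1, n_duplicate_pairs = 0, seed = 1)
  params <- run_parameters(seed = 1, rt_c_range = c(1.5, 1.5))
  truth <- simulate_true_concentrations(db, plan, params)
  expect_error(simulate_eics(db, plan, truth, params),
               "outside the EIC span")
})

test_that("QC intensities are conserved exactly without drift and noise", {
  run <- do.call(small_run, c(list(n_study = 40, n_batches = 2,
                                   n_lipids = 4),
                              quiet_params()))
  qc_ids <- run$plan$sample_id[run$plan$sample_type == "qc"]
  h <- run$eics$true_heights[qc_ids, , drop = FALSE]
  manual <- run$truth$concentrations[run$db$lipid_id, qc_ids[1]] *
    run$truth$response
  for (q in qc_ids)
    expect_equal(unname(h[q, ]), unname(manual), tolerance = 1e-12)
})

test_that("median QC RSD grows with the simulated noise CV", {
  meds <- vapply(c(0.02, 0.08, 0.20), function(cv) {
    run <- small_run(n_study = 80, n_batches = 2, n_lipids = 5,
                     noise_cv = cv, drift_amplitude = 0, seed = 21)
    fm <- extract_features(run$eics)
    stats::median(qc_rsd(fm), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("write_run/read_run round trip is lossless and deterministic", {
  run <- small_run(n_study = 12, n_batches = 1, n_lipids = 3, seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_run(run$eics, d1, truth = run$truth)
  expect_error(write_run(run$eics, d1), "not empty")
  write_run(run$eics, d2, truth = run$truth)

  # file census: one EIC per injection plus plan, database, ground truth
  expect_identical(length(dir(d1)), nrow(run$plan) + 3L)
  h1 <- unname(tools::md5sum(file.path(d1, sort(dir(d1)))))
  h2 <- unname(tools::md5sum(file.path(d2, sort(dir(d2)))))
  expect_identical(h1, h2)

  back <- read_run(d1)
  expect_identical(back$plan$sample_id, run$plan$sample_id)
  expect_identical(back$plan$duplicate_of, run$plan$duplicate_of)
  expect_equal(back$offsets, run$eics$offsets, tolerance = 1e-12)
  for (sid in run$plan$sample_id)
    expect_identical(back$intensity[[sid]], run$eics$intensity[[sid]])
  expect_identical(back$truth$concentrations, run$truth$concentrations)
  expect_identical(back$truth$rt_coefficients, run$truth$rt_coefficients)
})
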