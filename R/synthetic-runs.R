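# Synthetic multi-batch LC-MS run generator.
#
# Emulates the acquisition design the downstream pipeline expects: study
# samples analyzed in contiguous batches, one pooled-plasma QC after every
# block of study samples, one extraction blank per block, randomly inserted
# duplicate pairs, smooth per-batch multiplicative intensity drift, a
# per-sample quadratic retention-time distortion, Gaussian chromatographic
# peaks on a noisy baseline, and lognormal measurement noise. Every stochastic
# element is recorded as ground truth so downstream stages can be tested for
# exact recovery.

#' Parameters of a synthetic run
#'
#' @param seed Master seed; stage randomness (plan, concentrations, noise)
#'   flows from named sub-streams derived from it.
#' @param drift_amplitude Maximum per-batch drift excursion as a fraction of
#'   the mean response (0.2 = up to +/-20 percent across a batch).
#' @param drift_shape `"linear"` or `"quadratic"` within-batch drift curve.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise applied per peak (0.08 = 8 percent).
#' @param rt_a_range,rt_b_range,rt_c_range Uniform ranges for the per-sample
#'   quadratic RT distortion `observed = a rt^2 + b rt + c` (minutes). The
#'   defaults keep the total shift under half the 0.2-min peak-search window
#'   across a 15-min gradient, as a well-behaved UHPLC system does; larger
#'   shifts push internal standards onto their window boundaries and bias
#'   the recalibration.
#' @param peak_width_sd Chromatographic peak standard deviation, minutes.
#' @param baseline_level,baseline_noise Baseline counts and the half-width of
#'   its uniform noise.
#' @param carryover_fraction Blank signal as a fraction of the immediately
#'   preceding QC's peak heights.
#' @param rt_grid_step EIC sampling interval, minutes (0.005 min matches an
#'   acquisition rate of about 2 spectra per second over a 15-min gradient).
#' @param is_level Constant spiked amount of each internal standard.
#' @param lipid_mean_log,lipid_sdlog Lognormal hyper-parameters of per-lipid
#'   mean abundance.
#' @param biological_sdlog Between-subject lognormal spread per lipid.
#' @param qc_pool_sdlog Lognormal offset of the fixed QC pool level from the
#'   lipid mean (the pool is one plasma lot, not the study average).
#' @param response_sdlog Lognormal spread of per-adduct response factors.
#' @return A `run_parameters` list.
#' @export
run_parameters <- function(seed = 1L,
                           drift_amplitude = 0.20,
                           drift_shape = c("linear", "quadratic"),
                           noise_cv = 0.08,
                           rt_a_range = c(-2e-4, 2e-4),
                           rt_b_range = c(0.997, 1.003),
                           rt_c_range = c(-0.01, 0.01),
                           peak_width_sd = 0.02,
                           baseline_level = 50,
                           baseline_noise = 10,
                           carryover_fraction = 0.01,
                           rt_grid_step = 0.005,
                           is_level = 1e5,
                           lipid_mean_log = log(5e4),
                           lipid_sdlog = 1.0,
                           biological_sdlog = 0.4,
                           qc_pool_sdlog = 0.25,
                           response_sdlog = 0.3) {
  drift_shape <- match.arg(drift_shape)
  stopifnot(drift_amplitude >= 0, noise_cv >= 0, peak_width_sd > 0,
            baseline_level >= 0, baseline_noise >= 0,
            carryover_fraction >= 0, rt_grid_step > 0, is_level > 0)
  structure(list(
    seed = as.integer(seed), drift_amplitude = drift_amplitude,
    drift_shape = drift_shape, noise_cv = noise_cv,
    rt_a_range = rt_a_range, rt_b_range = rt_b_range,
    rt_c_range = rt_c_range, peak_width_sd = peak_width_sd,
    baseline_level = baseline_level, baseline_noise = baseline_noise,
    carryover_fraction = carryover_fraction, rt_grid_step = rt_grid_step,
    is_level = is_level, lipid_mean_log = lipid_mean_log,
    lipid_sdlog = lipid_sdlog, biological_sdlog = biological_sdlog,
    qc_pool_sdlog = qc_pool_sdlog, response_sdlog = response_sdlog
  ), class = "run_parameters")
}

#' Generate a synthetic target-ion database
#'
#' Lipids are detectable as one or two adducts per ionization mode; a
#' configurable fraction is detectable in both modes with, by construction,
#' correlated signals (shared concentration, different response factors).
#' Expected retention times are snapped to the EIC grid step so simulated
#' traces align exactly with file grids.
#'
#' @param n_lipids Number of analyte lipids.
#' @param n_internal_standards Internal standards per mode (>= 3 required by
#'   the quadratic RT recalibration).
#' @param dual_mode_fraction Fraction of lipids present in both modes.
#' @param two_adduct_fraction Fraction of (lipid, mode) entries with a second
#'   adduct.
#' @param known_unknown_fraction Fraction of lipids left unannotated (m/z and
#'   RT only, empty InChIKey).
#' @param rt_range Retention-time range (minutes) over which lipids elute.
#' @param rt_grid_step Grid step used to snap expected RTs.
#' @param seed Seed for the database draw.
#' @return An [ion_database()].
#' @export
synthetic_ion_database <- function(n_lipids = 30L,
                                   n_internal_standards = 4L,
                                   dual_mode_fraction = 0.4,
                                   two_adduct_fraction = 0.5,
                                   known_unknown_fraction = 0.2,
                                   rt_range = c(1.5, 13.5),
                                   rt_grid_step = 0.005,
                                   seed = 1L) {
  stopifnot(n_lipids >= 1, n_internal_standards >= 3)
  set.seed(derive_seed(seed, "database"))
  pos_adducts <- c("[M+H]+", "[M+NH4]+", "[M+Na]+")
  neg_adducts <- c("[M-H]-", "[M+OAc]-")
  snap <- function(rt) round(rt / rt_grid_step) * rt_grid_step

  rows <- list()
  add_row <- function(lipid_id, name, mode, adduct, mz, rt, inchikey,
                      is_is, is_known) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ion_id = sprintf("%s_%s_%s", lipid_id,
                       if (mode == "positive") "pos" else "neg",
                       gsub("[^A-Za-z0-9]", "", adduct)),
      lipid_id = lipid_id, name = name, mode = mode, adduct = adduct,
      mz = mz, expected_rt = rt, inchikey = inchikey,
      is_internal_standard = is_is, is_known = is_known,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_lipids)) {
    lid <- sprintf("LIP%03d", i)
    known <- stats::runif(1) >= known_unknown_fraction
    name <- if (known) sprintf("Lipid(%d:%d)", 30 + i %% 30, i %% 7)
            else sprintf("unknown_%03d", i)
    ik <- if (known) sprintf("SYNKEY%08d-SYNTHAOYSA-N", i) else ""
    rt <- snap(stats::runif(1, rt_range[1], rt_range[2]))
    base_mz <- stats::runif(1, 250, 1050)
    dual <- stats::runif(1) < dual_mode_fraction
    modes <- if (dual) c("positive", "negative")
             else sample(c("positive", "negative"), 1)
    for (mode in modes) {
      pool <- if (mode == "positive") pos_adducts else neg_adducts
      n_add <- 1L + (stats::runif(1) < two_adduct_fraction &&
                       length(pool) > 1L)
      for (adduct in sample(pool, n_add)) {
        i_add <- match(adduct, ADDUCT_TABLE$adduct)
        add_row(lid, name, mode, adduct,
                round(base_mz + ADDUCT_TABLE$delta[i_add], 4), rt, ik,
                FALSE, known)
      }
    }
  }

  # Internal standards: spread across the gradient so the quadratic RT fit
  # is well conditioned; one adduct each, always known.
  for (mode in c("positive", "negative")) {
    rts <- snap(seq(rt_range[1] + 0.3, rt_range[2] - 0.3,
                    length.out = n_internal_standards))
    for (j in seq_len(n_internal_standards)) {
      lid <- sprintf("ISTD%s%02d", if (mode == "positive") "P" else "N", j)
      add_row(lid, sprintf("iSTD %s %02d", mode, j), mode,
              if (mode == "positive") "[M+H]+" else "[M-H]-",
              round(stats::runif(1, 250, 1050), 4), rts[j],
              sprintf("ISYNKEY%07d-SYNTHAOYSA-N", j), TRUE, TRUE)
    }
  }

  ion_database(do.call(rbind, rows))
}

#' Build an injection sequence
#'
#' Study samples are randomized across contiguous batches whose sizes are
#' near-equal whole multiples of `qc_interval` (a remainder block goes to the
#' last batch and is closed by a trailing QC). After every `qc_interval`
#' study samples a pooled QC is injected, followed by a blank after every
#' `blank_interval` study samples. `n_duplicate_pairs` of the study
#' injections are replicate aliquots of another study sample, linked through
#' `duplicate_of`.
#'
#' @param n_study Number of study injections (replicates included).
#' @param n_batches Number of batches.
#' @param qc_interval Study samples per QC injection.
#' @param blank_interval Study samples per blank injection.
#' @param n_duplicate_pairs Number of replicate pairs among the study
#'   injections.
#' @param seed Seed for randomization.
#' @return An `injection_plan`: data frame with `sample_id`, `sample_type`
#'   (`study`/`qc`/`blank`), `batch`, `injection_order`, `duplicate_of`, with
#'   the design recorded in attributes.
#' @export
build_injection_sequence <- function(n_study, n_batches = 4L,
                                     qc_interval = 10L, blank_interval = 10L,
                                     n_duplicate_pairs = 20L, seed = 1L) {
  stopifnot(is_count(n_study), n_study >= 1, is_count(n_batches),
            n_batches >= 1, is_count(qc_interval), qc_interval >= 1,
            is_count(blank_interval), blank_interval >= 1)
  if (n_duplicate_pairs > n_study / 2)
    abort("n_duplicate_pairs (%d) cannot exceed half of n_study (%d)",
          n_duplicate_pairs, n_study)
  set.seed(derive_seed(seed, "plan"))

  # Subject identities: originals plus replicate aliquots of a random subset.
  n_subjects <- n_study - n_duplicate_pairs
  subjects <- sprintf("S%04d", seq_len(n_subjects))
  dup_sources <- sort(sample(subjects, n_duplicate_pairs))
  ids <- c(subjects, paste0(dup_sources, "R", recycle0 = TRUE))
  dup_of <- c(rep(NA_character_, n_subjects), dup_sources)
  ord <- sample.int(length(ids))
  ids <- ids[ord]; dup_of <- dup_of[ord]

  # Batch sizes: whole blocks of qc_interval distributed evenly, remainder
  # block appended to the last batch.
  n_blocks <- n_study %/% qc_interval
  rem <- n_study %% qc_interval
  if (n_blocks < n_batches && n_study >= n_batches) {
    sizes <- diff(floor(seq(0, n_study, length.out = n_batches + 1)))
  } else {
    blocks <- rep(n_blocks %/% n_batches, n_batches)
    extra <- n_blocks %% n_batches
    if (extra > 0) blocks[seq_len(extra)] <- blocks[seq_len(extra)] + 1L
    sizes <- blocks * qc_interval
    sizes[n_batches] <- sizes[n_batches] + rem
  }

  rec <- list(); n_qc <- 0L; n_blank <- 0L
  push <- function(id, type, batch, dup = NA_character_) {
    rec[[length(rec) + 1L]] <<- data.frame(
      sample_id = id, sample_type = type, batch = batch,
      duplicate_of = dup, stringsAsFactors = FALSE)
  }
  k <- 0L
  for (b in seq_len(n_batches)) {
    since_qc <- 0L; since_blank <- 0L
    for (j in seq_len(sizes[b])) {
      k <- k + 1L
      push(ids[k], "study", b, dup_of[k])
      since_qc <- since_qc + 1L; since_blank <- since_blank + 1L
      if (since_qc == qc_interval) {
        n_qc <- n_qc + 1L
        push(sprintf("QC%03d", n_qc), "qc", b)
        since_qc <- 0L
      }
      if (since_blank == blank_interval) {
        n_blank <- n_blank + 1L
        push(sprintf("BLK%03d", n_blank), "blank", b)
        since_blank <- 0L
      }
    }
    # Close a trailing partial block so every study sample is bracketed.
    if (since_qc > 0L) {
      n_qc <- n_qc + 1L
      push(sprintf("QC%03d", n_qc), "qc", b)
    }
    if (since_blank > 0L) {
      n_blank <- n_blank + 1L
      push(sprintf("BLK%03d", n_blank), "blank", b)
    }
  }

  plan <- do.call(rbind, rec)
  plan$injection_order <- seq_len(nrow(plan))
  plan <- plan[c("sample_id", "sample_type", "batch", "injection_order",
                 "duplicate_of")]
  structure(plan,
            class = c("injection_plan", "data.frame"),
            n_batches = n_batches, qc_interval = qc_interval,
            blank_interval = blank_interval,
            duplicate_pairs = data.frame(
              original = dup_sources,
              replicate = paste0(dup_sources, "R", recycle0 = TRUE),
              stringsAsFactors = FALSE))
}

#' @export
print.injection_plan <- function(x, ...) {
  tab <- table(x$sample_type)
  cat(sprintf(
    "<injection_plan> %d injections in %d batches (%s)\n", nrow(x),
    attr(x, "n_batches"),
    paste(names(tab), as.integer(tab), sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Simulate ground-truth concentrations, drift curves and RT distortions
#'
#' Study-sample lipid levels are lognormal around per-lipid means; the QC
#' pool level is one fixed draw per lipid; duplicate pairs share their
#' originals' levels; every adduct of a lipid shares the lipid concentration
#' scaled by a fixed per-ion response factor (which is what makes dual-mode
#' signals correlated). Internal standards are spiked at a constant level in
#' every non-blank sample.
#'
#' @param db An [ion_database()].
#' @param plan An [build_injection_sequence()] plan.
#' @param params [run_parameters()].
#' @param seed Optional override of the concentration sub-stream seed
#'   (defaults to `params$seed`).
#' @return A `ground_truth` list: `concentrations` (lipids x non-blank
#'   samples), `response` (per ion), `drift_slopes` (ions x batches),
#'   `drift_shape`, `rt_coefficients` (per sample a, b, c).
#' @export
simulate_true_concentrations <- function(db, plan, params, seed = NULL) {
  stopifnot(inherits(db, "ion_database"), inherits(plan, "injection_plan"),
            inherits(params, "run_parameters"))
  set.seed(derive_seed(if (is.null(seed)) params$seed else seed,
                       "concentrations"))

  lipids <- unique(db$lipid_id)
  is_lipid <- unique(db$lipid_id[db$is_internal_standard])
  analytes <- setdiff(lipids, is_lipid)
  nonblank <- plan$sample_id[plan$sample_type != "blank"]

  lipid_mean <- stats::setNames(
    exp(stats::rnorm(length(analytes), params$lipid_mean_log,
                     params$lipid_sdlog)), analytes)
  qc_level <- lipid_mean *
    exp(stats::rnorm(length(analytes), 0, params$qc_pool_sdlog))

  conc <- matrix(NA_real_, length(lipids), length(nonblank),
                 dimnames = list(lipids, nonblank))
  study <- plan[plan$sample_type == "study", ]
  originals <- study$sample_id[is.na(study$duplicate_of)]
  for (l in analytes) {
    conc[l, originals] <- lipid_mean[l] *
      exp(stats::rnorm(length(originals), 0, params$biological_sdlog))
    conc[l, plan$sample_id[plan$sample_type == "qc"]] <- qc_level[l]
  }
  dup <- study[!is.na(study$duplicate_of), ]
  if (nrow(dup)) conc[, dup$sample_id] <- conc[, dup$duplicate_of]
  conc[is_lipid, ] <- params$is_level

  response <- stats::setNames(
    exp(stats::rnorm(nrow(db), 0, params$response_sdlog)), db$ion_id)

  n_batches <- attr(plan, "n_batches")
  drift_slopes <- matrix(
    stats::runif(nrow(db) * n_batches, -params$drift_amplitude,
                 params$drift_amplitude),
    nrow(db), n_batches, dimnames = list(db$ion_id, NULL))

  rt_coefficients <- data.frame(
    sample_id = plan$sample_id,
    a = stats::runif(nrow(plan), params$rt_a_range[1], params$rt_a_range[2]),
    b = stats::runif(nrow(plan), params$rt_b_range[1], params$rt_b_range[2]),
    c = stats::runif(nrow(plan), params$rt_c_range[1], params$rt_c_range[2]),
    stringsAsFactors = FALSE)

  structure(list(concentrations = conc, response = response,
                 drift_slopes = drift_slopes,
                 drift_shape = params$drift_shape,
                 rt_coefficients = rt_coefficients,
                 lipid_mean = lipid_mean, qc_level = qc_level),
            class = "ground_truth")
}

# Multiplicative drift at a position within a batch (`pos` in [0, 1]).
# Curves start each batch at the nominal response (source cleaned / retuned)
# and drift away by up to the amplitude, so batches also end at different
# mean levels -- the between-batch offsets that median normalization
# removes.
drift_curve_value <- function(slope, pos, shape) {
  switch(shape,
         linear = 1 + slope * pos,
         quadratic = 1 + slope * pos^2,
         abort("unknown drift shape '%s'", shape))
}

#' Drift multiplier for given ions at given injections
#'
#' @param truth A [simulate_true_concentrations()] ground truth.
#' @param plan The injection plan.
#' @param ion_id Ion identifier(s).
#' @param injection_order Injection order(s), recycled against `ion_id`.
#' @return Numeric multiplier(s).
#' @export
drift_multiplier <- function(truth, plan, ion_id, injection_order) {
  batch <- plan$batch[match(injection_order, plan$injection_order)]
  rng <- tapply(plan$injection_order, plan$batch, range)
  pos <- vapply(seq_along(injection_order), function(i) {
    r <- rng[[as.character(batch[i])]]
    if (r[2] == r[1]) 0.5 else (injection_order[i] - r[1]) / (r[2] - r[1])
  }, numeric(1))
  s <- truth$drift_slopes[cbind(match(ion_id, rownames(truth$drift_slopes)),
                                batch)]
  drift_curve_value(s, pos, truth$drift_shape)
}

#' Simulate per-sample extracted ion chromatograms
#'
#' For every sample and target ion the EIC spans `expected_rt` +/- 1 min at
#' `rt_grid_step`: a Gaussian peak centered at the sample's distorted true RT
#' with height `concentration x response x drift x lognormal noise` on a
#' noisy baseline. Blanks contain `carryover_fraction` times the immediately
#' preceding QC's peak heights, plus baseline.
#'
#' @param db,plan,truth,params Database, plan, ground truth, parameters.
#' @return An `eic_set`: `offsets` (shared grid of RT offsets from each ion's
#'   expected RT), `intensity` (per sample, a grid x ions matrix), `db`,
#'   `plan`, and the realized `true_heights` and `true_apex_rt` matrices.
#' @export
simulate_eics <- function(db, plan, truth, params) {
  stopifnot(inherits(db, "ion_database"), inherits(plan, "injection_plan"),
            inherits(truth, "ground_truth"),
            inherits(params, "run_parameters"))
  set.seed(derive_seed(params$seed, "noise"))

  offsets <- seq(-1, 1, by = params$rt_grid_step)
  n_ion <- nrow(db)
  sdlog <- sqrt(log(1 + params$noise_cv^2))

  # Distorted apex RT per (sample, ion): a rt^2 + b rt + c.
  rc <- truth$rt_coefficients[match(plan$sample_id,
                                    truth$rt_coefficients$sample_id), ]
  ert <- db$expected_rt
  intensity <- vector("list", nrow(plan))
  names(intensity) <- plan$sample_id
  true_heights <- matrix(0, nrow(plan), n_ion,
                         dimnames = list(plan$sample_id, db$ion_id))
  true_apex <- matrix(NA_real_, nrow(plan), n_ion,
                      dimnames = list(plan$sample_id, db$ion_id))
  last_qc_height <- NULL; last_qc_apex <- NULL

  for (i in seq_len(nrow(plan))) {
    sid <- plan$sample_id[i]
    type <- plan$sample_type[i]
    if (type == "blank") {
      if (params$carryover_fraction > 0 && !is.null(last_qc_height)) {
        height <- params$carryover_fraction * last_qc_height
        apex <- last_qc_apex
      } else {
        height <- rep(0, n_ion)
        apex <- ert  # no carryover signal; center is immaterial
      }
    } else {
      apex <- rc$a[i] * ert^2 + rc$b[i] * ert + rc$c[i]
      off <- apex - ert
      bad <- which(abs(off) > 1 - 2 * params$peak_width_sd)
      if (length(bad))
        abort("distorted RT outside the EIC span for ion(s): %s",
              paste(db$ion_id[bad], collapse = ", "))
      noise <- if (params$noise_cv > 0)
        exp(stats::rnorm(n_ion, -sdlog^2 / 2, sdlog)) else rep(1, n_ion)
      height <- truth$concentrations[db$lipid_id, sid] *
        truth$response * drift_multiplier(truth, plan, db$ion_id,
                                          rep(plan$injection_order[i], n_ion)) *
        noise
      if (type == "qc") { last_qc_height <- height; last_qc_apex <- apex }
    }
    shift <- apex - ert  # peak center relative to each ion's own grid
    g <- exp(-(outer(offsets, shift, "-"))^2 / (2 * params$peak_width_sd^2))
    mat <- sweep(g, 2L, height, "*")
    if (params$baseline_level > 0 || params$baseline_noise > 0)
      mat <- mat + params$baseline_level +
        stats::runif(length(mat), 0, params$baseline_noise)
    dimnames(mat) <- list(NULL, db$ion_id)
    intensity[[sid]] <- mat
    true_heights[sid, ] <- height
    true_apex[sid, ] <- apex
  }

  structure(list(offsets = offsets, intensity = intensity, db = db,
                 plan = plan, true_heights = true_heights,
                 true_apex_rt = true_apex, params = params),
            class = "eic_set")
}

#' @export
print.eic_set <- function(x, ...) {
  cat(sprintf("<eic_set> %d samples x %d ions, %d RT points per trace\n",
              length(x$intensity), nrow(x$db), length(x$offsets)))
  invisible(x)
}

#' Retrieve one EIC trace
#'
#' @param eics An `eic_set`.
#' @param sample_id,ion_id Identifiers.
#' @return Data frame with `rt` (absolute minutes) and `intensity`.
#' @export
eic_trace <- function(eics, sample_id, ion_id) {
  j <- match(ion_id, eics$db$ion_id)
  if (is.na(j)) abort("unknown ion_id '%s'", ion_id)
  m <- eics$intensity[[sample_id]]
  if (is.null(m)) abort("unknown sample_id '%s'", sample_id)
  data.frame(rt = eics$db$expected_rt[j] + eics$offsets,
             intensity = m[, j])
}

#' Write a synthetic run to disk
#'
#' Emits one EIC CSV per sample (first column `rt_min` on a global grid, one
#' column per ion, empty outside an ion's +/- 1 min span), plus `plan.csv`,
#' `database.csv` and `ground_truth.csv`. All files re-load losslessly with
#' [read_run()].
#'
#' @param eics An `eic_set` from [simulate_eics()].
#' @param out_dir Output directory.
#' @param truth Optional ground truth to serialize alongside.
#' @param overwrite Overwrite an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(eics, out_dir, truth = NULL, overwrite = FALSE) {
  stopifnot(inherits(eics, "eic_set"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    abort("directory %s exists and is not empty (use overwrite = TRUE)",
          out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- eics$db; step <- diff(eics$offsets[1:2])
  write_ion_database(db, file.path(out_dir, "database.csv"))
  plan_out <- as.data.frame(eics$plan)
  utils::write.csv(plan_out, file.path(out_dir, "plan.csv"),
                   row.names = FALSE, quote = TRUE, na = "")

  # Global grid covering every ion's span; expected RTs are grid-aligned.
  lo <- min(db$expected_rt) - 1; hi <- max(db$expected_rt) + 1
  grid <- seq(lo, hi, by = step)
  idx0 <- round((db$expected_rt - 1 - lo) / step)  # row offset per ion
  for (sid in names(eics$intensity)) {
    m <- eics$intensity[[sid]]
    out <- matrix(NA_real_, length(grid), nrow(db),
                  dimnames = list(NULL, db$ion_id))
    for (j in seq_len(nrow(db)))
      out[idx0[j] + seq_along(eics$offsets), j] <- m[, j]
    df <- data.frame(rt_min = sprintf("%.6f", grid))
    for (j in seq_len(nrow(db))) df[[db$ion_id[j]]] <- format_full(out[, j])
    df[df == "NA"] <- ""
    utils::write.csv(df, file.path(out_dir, sprintf("eic_%s.csv", sid)),
                     row.names = FALSE, quote = FALSE, na = "")
  }

  if (!is.null(truth)) {
    long <- rbind(
      data.frame(record = "concentration",
                 key1 = rep(rownames(truth$concentrations),
                            ncol(truth$concentrations)),
                 key2 = rep(colnames(truth$concentrations),
                            each = nrow(truth$concentrations)),
                 value = format_full(as.vector(truth$concentrations)),
                 stringsAsFactors = FALSE),
      data.frame(record = "response", key1 = names(truth$response),
                 key2 = "", value = format_full(unname(truth$response))),
      data.frame(record = "drift_slope",
                 key1 = rep(rownames(truth$drift_slopes),
                            ncol(truth$drift_slopes)),
                 key2 = as.character(rep(seq_len(ncol(truth$drift_slopes)),
                                         each = nrow(truth$drift_slopes))),
                 value = format_full(as.vector(truth$drift_slopes))),
      data.frame(record = "drift_shape", key1 = "", key2 = "",
                 value = truth$drift_shape),
      data.frame(record = "rt_coefficient",
                 key1 = rep(truth$rt_coefficients$sample_id, 3),
                 key2 = rep(c("a", "b", "c"),
                            each = nrow(truth$rt_coefficients)),
                 value = format_full(c(truth$rt_coefficients$a,
                                       truth$rt_coefficients$b,
                                       truth$rt_coefficients$c))))
    utils::write.csv(long, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE, quote = TRUE)
  }
  invisible(out_dir)
}

#' Read a synthetic run back from disk
#'
#' @param run_dir Directory written by [write_run()].
#' @return An `eic_set` (with `truth` attached when `ground_truth.csv` is
#'   present).
#' @export
read_run <- function(run_dir) {
  db <- load_ion_database(file.path(run_dir, "database.csv"))
  plan <- utils::read.csv(file.path(run_dir, "plan.csv"),
                          stringsAsFactors = FALSE, na.strings = "")
  plan$duplicate_of <- as.character(plan$duplicate_of)
  qcs <- grepl("^QC", plan$sample_id)
  plan <- structure(plan, class = c("injection_plan", "data.frame"),
                    n_batches = max(plan$batch))

  files <- file.path(run_dir, sprintf("eic_%s.csv", plan$sample_id))
  missing_files <- !file.exists(files)
  if (any(missing_files))
    abort("missing EIC file(s): %s",
          paste(basename(files[missing_files]), collapse = ", "))

  first <- utils::read.csv(files[1], check.names = FALSE,
                           na.strings = c("NA", ""))
  grid <- first$rt_min
  step <- round(grid[2] - grid[1], 9)
  offsets <- seq(-1, 1, by = step)
  idx0 <- round((db$expected_rt - 1 - grid[1]) / step)

  intensity <- vector("list", nrow(plan))
  names(intensity) <- plan$sample_id
  for (i in seq_len(nrow(plan))) {
    tab <- utils::read.csv(files[i], check.names = FALSE,
                           na.strings = c("NA", ""))
    m <- matrix(NA_real_, length(offsets), nrow(db),
                dimnames = list(NULL, db$ion_id))
    for (j in seq_len(nrow(db)))
      m[, j] <- as.numeric(tab[[db$ion_id[j]]][idx0[j] +
                                                 seq_along(offsets)])
    intensity[[i]] <- m
  }

  truth <- NULL
  tf <- file.path(run_dir, "ground_truth.csv")
  if (file.exists(tf)) {
    long <- utils::read.csv(tf, stringsAsFactors = FALSE, na.strings = NULL)
    pick <- function(rec) long[long$record == rec, , drop = FALSE]
    co <- pick("concentration")
    lipids <- unique(co$key1); samples <- unique(co$key2)
    conc <- matrix(NA_real_, length(lipids), length(samples),
                   dimnames = list(lipids, samples))
    conc[cbind(co$key1, co$key2)] <- as.numeric(co$value)
    rs <- pick("response")
    ds <- pick("drift_slope")
    slopes <- matrix(NA_real_, length(unique(ds$key1)),
                     max(as.integer(ds$key2)),
                     dimnames = list(unique(ds$key1), NULL))
    slopes[cbind(match(ds$key1, rownames(slopes)),
                 as.integer(ds$key2))] <- as.numeric(ds$value)
    rcL <- pick("rt_coefficient")
    sids <- unique(rcL$key1)
    getc <- function(kk) {
      sub <- rcL[rcL$key2 == kk, ]
      as.numeric(sub$value)[match(sids, sub$key1)]
    }
    truth <- structure(list(
      concentrations = conc,
      response = stats::setNames(as.numeric(rs$value), rs$key1),
      drift_slopes = slopes, drift_shape = pick("drift_shape")$value,
      rt_coefficients = data.frame(sample_id = sids, a = getc("a"),
                                   b = getc("b"), c = getc("c"),
                                   stringsAsFactors = FALSE)),
      class = "ground_truth")
  }

  structure(list(offsets = offsets, intensity = intensity, db = db,
                 plan = plan, truth = truth),
            class = "eic_set")
}
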