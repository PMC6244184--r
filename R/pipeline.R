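# Stage orchestration: simulate -> extract -> normalize -> filter -> report,
# driven by one validated config whose seed feeds every source of
# randomness. Each stage is also callable on its own; composing the five
# stages equals the monolithic run.

#' Build a validated pipeline configuration
#'
#' The config is the single source of parameters for [run_pipeline()] and
#' the stage commands; it serializes losslessly to YAML.
#'
#' @param ... Overrides of the defaults (see the returned list for names).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_study = 200L, n_batches = 4L, qc_interval = 10L, blank_interval = 10L,
    n_duplicate_pairs = 20L,
    n_lipids = 30L, n_internal_standards = 4L,
    dual_mode_fraction = 0.4, two_adduct_fraction = 0.5,
    known_unknown_fraction = 0.2,
    drift_amplitude = 0.20, drift_shape = "linear", noise_cv = 0.08,
    peak_width_sd = 0.02, baseline_level = 50, baseline_noise = 10,
    carryover_fraction = 0.01, rt_grid_step = 0.005,
    window = 0.20, span_grid = seq(0.3, 1.0, by = 0.1),
    rsd_threshold = 25, cv_folds = 5L, carryover_threshold = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_study >= 1, cfg$n_batches >= 1, cfg$qc_interval >= 1,
            cfg$window > 0, cfg$rsd_threshold > 0, cfg$cv_folds >= 2,
            all(cfg$span_grid > 0 & cfg$span_grid <= 1))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()]: a validated `pipeline_config`;
#'   [write_pipeline_config()]: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(config) {
  run_parameters(
    seed = config$seed, drift_amplitude = config$drift_amplitude,
    drift_shape = config$drift_shape, noise_cv = config$noise_cv,
    peak_width_sd = config$peak_width_sd,
    baseline_level = config$baseline_level,
    baseline_noise = config$baseline_noise,
    carryover_fraction = config$carryover_fraction,
    rt_grid_step = config$rt_grid_step)
}

#' Pipeline stage: simulate a synthetic run
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory to persist the run via [write_run()].
#' @param overwrite Passed to [write_run()].
#' @return List with `db`, `plan`, `truth`, `eics`, `params`.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir = NULL,
                         overwrite = FALSE) {
  params <- config_params(config)
  db <- synthetic_ion_database(
    n_lipids = config$n_lipids,
    n_internal_standards = config$n_internal_standards,
    dual_mode_fraction = config$dual_mode_fraction,
    two_adduct_fraction = config$two_adduct_fraction,
    known_unknown_fraction = config$known_unknown_fraction,
    rt_grid_step = config$rt_grid_step, seed = config$seed)
  plan <- build_injection_sequence(
    config$n_study, config$n_batches, config$qc_interval,
    config$blank_interval, config$n_duplicate_pairs, seed = config$seed)
  truth <- simulate_true_concentrations(db, plan, params)
  eics <- simulate_eics(db, plan, truth, params)
  if (!is.null(out_dir))
    write_run(eics, out_dir, truth = truth, overwrite = overwrite)
  list(db = db, plan = plan, truth = truth, eics = eics, params = params)
}

#' Pipeline stage: extract the raw peak-height matrix
#'
#' @param run A [run_simulate()] result, an `eic_set`, or a run directory.
#' @param config A [pipeline_config()].
#' @return A raw [feature_matrix()].
#' @export
run_extract <- function(run, config = pipeline_config()) {
  eics <- if (inherits(run, "eic_set")) run
          else if (is.list(run) && inherits(run$eics, "eic_set")) run$eics
          else if (is.character(run)) read_run(run)
          else abort("run must be an eic_set, a simulate result, or a path")
  extract_features(eics, window = config$window)
}

#' Pipeline stage: normalize the raw matrix
#'
#' LOESS drift correction, cross-batch median normalization and the k-fold
#' cross-validated QC RSD performance metric.
#'
#' @param fm Raw [feature_matrix()].
#' @param config A [pipeline_config()].
#' @return List with `matrix`, `audit`, `cv_rsd`.
#' @export
run_normalize <- function(fm, config = pipeline_config()) {
  norm <- normalize_features(fm, span_grid = config$span_grid)
  cv <- tryCatch(cv_rsd(fm, k = config$cv_folds,
                        span_grid = config$span_grid),
                 error = function(e) NULL)
  list(matrix = norm$matrix, audit = norm$audit, cv_rsd = cv)
}

#' Pipeline stage: deduplicate and filter to the final lipid matrix
#'
#' @param fm Normalized [feature_matrix()].
#' @param db The [ion_database()].
#' @param config A [pipeline_config()].
#' @return List with `matrix`, `dictionary`, `dedup`, `removed`,
#'   `dropped_modes`.
#' @export
run_filter <- function(fm, db, config = pipeline_config()) {
  rsds <- qc_rsd(fm)
  sel <- select_adduct_within_mode(db, rsds)
  dedup <- dedup_across_modes(sel, fm)
  final <- finalize_lipid_matrix(fm, dedup, threshold = config$rsd_threshold)
  list(matrix = final$matrix,
       dictionary = build_data_dictionary(final$matrix, db),
       dedup = dedup, removed = final$removed,
       dropped_modes = sel$dropped)
}

#' Pipeline stage: technical-validation report
#'
#' @param raw_fm,norm_fm Raw and normalized feature matrices.
#' @param eics Optional `eic_set` for the carryover check.
#' @param config A [pipeline_config()].
#' @return A [qc_report()].
#' @export
run_report <- function(raw_fm, norm_fm, eics = NULL,
                       config = pipeline_config()) {
  qc_report(raw_fm, norm_fm, eics = eics,
            carryover_threshold = config$carryover_threshold)
}

#' Run the full pipeline end to end
#'
#' Equals the composition of the five stage commands on the same config.
#' With `out_dir` set, writes the raw and normalized matrices, the
#' normalization audit, the final matrix and dictionary, and the QC report
#' tables; outputs are byte-identical across runs with the same config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `run`, `raw`, `normalized`, `filtered`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  run <- run_simulate(config)
  raw <- run_extract(run, config)
  normalized <- run_normalize(raw, config)
  filtered <- run_filter(normalized$matrix, run$db, config)
  report <- run_report(raw, normalized$matrix, eics = run$eics,
                       config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_matrix(raw, file.path(out_dir, "raw"))
    write_feature_matrix(normalized$matrix, file.path(out_dir, "normalized"))
    utils::write.csv(normalized$audit,
                     file.path(out_dir, "normalization_audit.csv"),
                     row.names = FALSE)
    if (!is.null(normalized$cv_rsd))
      utils::write.csv(data.frame(ion_id = names(normalized$cv_rsd),
                                  cv_rsd = unname(normalized$cv_rsd)),
                       file.path(out_dir, "cv_rsd.csv"), row.names = FALSE)
    write_final_matrix(list(matrix = filtered$matrix),
                       filtered$dictionary, file.path(out_dir, "lipids"))
    utils::write.csv(filtered$dedup, file.path(out_dir, "dedup.csv"),
                     row.names = FALSE)
    utils::write.csv(filtered$removed, file.path(out_dir, "removed.csv"),
                     row.names = FALSE)
    write_qc_report(report, file.path(out_dir, "qc_report"))
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  }
  list(run = run, raw = raw, normalized = normalized, filtered = filtered,
       report = report)
}
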