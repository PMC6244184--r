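# Shared fixtures: small synthetic databases and runs built in code, plus
# independent oracles used to cross-check the implementation.

tiny_db <- function(n_lipids = 6L, seed = 42L, ...) {
  synthetic_ion_database(n_lipids = n_lipids, n_internal_standards = 3L,
                         seed = seed, ...)
}

# A complete small run: database, plan, truth, EICs. Parameter overrides go
# to run_parameters(); plan arguments are explicit.
small_run <- function(n_study = 200L, n_batches = 4L, n_duplicate_pairs = 0L,
                      n_lipids = 8L, seed = 11L, ...) {
  db <- tiny_db(n_lipids = n_lipids, seed = seed)
  plan <- build_injection_sequence(n_study, n_batches,
                                   n_duplicate_pairs = n_duplicate_pairs,
                                   seed = seed)
  params <- run_parameters(seed = seed, ...)
  truth <- simulate_true_concentrations(db, plan, params)
  eics <- simulate_eics(db, plan, truth, params)
  list(db = db, plan = plan, params = params, truth = truth, eics = eics)
}

# Noise-free / drift-free / distortion-free overrides for exactness checks.
quiet_params <- function(...) {
  defaults <- list(noise_cv = 0, baseline_level = 0, baseline_noise = 0,
                   drift_amplitude = 0, carryover_fraction = 0,
                   rt_a_range = c(0, 0), rt_b_range = c(1, 1),
                   rt_c_range = c(0, 0))
  over <- list(...)
  defaults[names(over)] <- over
  defaults
}

# Independent tricube local-linear (LOESS, degree 1) oracle: q nearest
# neighbors, tricube weights, weighted least squares per evaluation point.
tricube_predict <- function(x, y, span, x_new) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x_new, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- pmax(0, 1 - pmin(d / dq, 1)^3)^3
    keep <- w > 0
    X <- cbind(1, x[keep] - x0)
    fit <- stats::lm.wfit(X, y[keep], w[keep])
    unname(fit$coefficients[1])
  }, numeric(1))
}

expect_no_internal_standards <- function(fm) {
  expect_false(any(fm$ions$is_internal_standard))
}
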