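# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

# small default-structure cohort for structural tests
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_cohort(
      generator_config(n_persons = 60, n_waves = 4, n_items = 12,
                       n_varying = 2, mcar_rate = 0.05, seed = 101))
  }
  .fixtures$small
}

# drift-free cohort with no covariate effects, for IRT recovery tests
irt_cohort <- function(n_persons = 300, n_items = 12, seed = 42,
                       drift_b = 0.3, drift_a = 0.1) {
  generate_cohort(generator_config(
    n_persons = n_persons, n_waves = 6, n_items = n_items, n_varying = 2,
    mcar_rate = 0.05, wave_drift_sd_b = drift_b, wave_drift_sd_a = drift_a,
    wave_effect_sd = 0.7, person_resid_sd = 0.7, factor_resid_sd = 0,
    covariate_effects = c(none = 0), seed = seed))
}

# ordinal data from a known first-order factor model:
# m factors, items_per_factor items each, uniform loadings, thresholds
# cutting the latent responses into n_cat categories
factor_model_data <- function(n, m, items_per_factor, loading = 0.7,
                              factor_cor = 0.3, n_cat = 3, seed = 1) {
  set.seed(seed)
  p <- m * items_per_factor
  phi <- matrix(factor_cor, m, m)
  diag(phi) <- 1
  f <- matrix(rnorm(n * m), n, m) %*% chol(phi)
  idx <- rep(seq_len(m), each = items_per_factor)
  eps <- matrix(rnorm(n * p), n, p)
  y <- loading * f[, idx] + sqrt(1 - loading^2) * eps
  cuts <- qnorm(seq_len(n_cat - 1) / n_cat)
  x <- apply(y, 2, function(col) {
    as.integer(cut(col, c(-Inf, cuts, Inf))) - 1L
  })
  colnames(x) <- sprintf("v%02d", seq_len(p))
  x
}

expect_strictly_increasing <- function(x) {
  expect_true(all(diff(x) > 0))
}
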