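#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic longitudinal cohort: panel
#' dimensions, factor structure, item-parameter drift across waves, the
#' wave/person variance decomposition of latent health, covariate effects
#' and outcome links. Defaults emulate a six-wave ageing-study panel with
#' 45 ordinal items (2-5 categories) loading on five correlated
#' first-order factors under one general factor, 39 anchor and 6
#' wave-varying items, and item-level MCAR missingness.
#'
#' The latent trait is coded as \emph{ill-health}: higher values mean
#' worse health, matching the item coding where higher categories mean
#' worse responses. The reversal to a "higher is better" score happens
#' only in \code{\link{to_health_score}}.
#'
#' @param n_persons number of persons.
#' @param n_waves number of waves (>= 2).
#' @param n_items number of ordinal items.
#' @param n_first_order_factors number of first-order factors the items
#'   load on.
#' @param n_varying number of wave-varying items, i.e. items not
#'   administered in at least one wave after the first. Must be strictly
#'   less than \code{n_items}.
#' @param n_crossload number of items assigned a secondary factor
#'   loading.
#' @param categories_per_item integer vector of response-category counts,
#'   recycled to \code{n_items}; all entries in 2..5.
#' @param mcar_rate probability in [0, 1) that an administered cell is
#'   missing completely at random.
#' @param wave_drift_sd_b standard deviation of the shared per-item-wave
#'   threshold offsets d_iw (waves after the first).
#' @param wave_drift_sd_a standard deviation of per-item-wave slope
#'   perturbations around the item slope (waves after the first).
#' @param wave_effect_sd standard deviation sigma_u of the wave random
#'   effect u_w on latent health.
#' @param person_resid_sd standard deviation sigma_theta of the
#'   person-wave residual e_pw (> 0).
#' @param factor_resid_sd loading of the person-level factor-specific
#'   residual on each item's liability (0 disables it). This is what
#'   gives the cohort its first-order factor structure: items of the
#'   same first-order factor share a person-level residual beyond the
#'   general health trait, so a factor screen finds the configured
#'   number of correlated first-order factors under the general factor.
#'   Cross-loading items pick up their secondary factor at half weight.
#' @param covariate_effects named numeric vector of per-level effects of
#'   the generated covariates on latent ill-health (see
#'   \code{\link{sample_covariates}} for the covariate set and coding).
#'   Positive values push toward worse health.
#' @param mortality_base baseline ten-year mortality probability at
#'   average latent health.
#' @param mortality_slope probit slope of baseline latent ill-health on
#'   mortality (> 0 means worse health raises mortality).
#' @param institution_base,institution_slope same for the
#'   institutionalisation outcome (smaller base rate).
#' @param chronic_base,chronic_slope length-8 vectors of probit
#'   intercepts (as probabilities) and slopes for the chronic-condition
#'   flags.
#' @param seed integer seed controlling every stochastic step.
#'
#' @return An object of class \code{"generator_config"} (a validated
#'   list).
#' @examples
#' cfg <- generator_config(n_persons = 50, seed = 1)
#' cfg$n_items
#' @export
generator_config <- function(n_persons = 500,
                             n_waves = 6,
                             n_items = 45,
                             n_first_order_factors = 5,
                             n_varying = 6,
                             n_crossload = 8,
                             categories_per_item = NULL,
                             mcar_rate = 0.05,
                             wave_drift_sd_b = 0.30,
                             wave_drift_sd_a = 0.10,
                             wave_effect_sd = 0.7,
                             person_resid_sd = 0.7,
                             factor_resid_sd = 0.5,
                             covariate_effects = NULL,
                             mortality_base = 0.20,
                             mortality_slope = NULL,
                             institution_base = 0.02,
                             institution_slope = NULL,
                             chronic_base = NULL,
                             chronic_slope = NULL,
                             seed = 1L) {
  if (is.null(categories_per_item)) {
    categories_per_item <- rep(c(4L, 3L, 2L, 5L, 3L), length.out = n_items)
  } else {
    categories_per_item <- rep(as.integer(categories_per_item),
                               length.out = n_items)
  }
  if (is.null(covariate_effects)) covariate_effects <- default_covariate_effects()
  if (is.null(chronic_base)) chronic_base <- c(0.10, 0.12, 0.35, 0.08, 0.04, 0.08, 0.09, 0.10)
  if (is.null(chronic_slope)) chronic_slope <- rep(0.25, 8)

  cfg <- list(
    n_persons = as.integer(n_persons), n_waves = as.integer(n_waves),
    n_items = as.integer(n_items),
    n_first_order_factors = as.integer(n_first_order_factors),
    n_varying = as.integer(n_varying), n_crossload = as.integer(n_crossload),
    categories_per_item = categories_per_item,
    mcar_rate = mcar_rate,
    wave_drift_sd_b = wave_drift_sd_b, wave_drift_sd_a = wave_drift_sd_a,
    wave_effect_sd = wave_effect_sd, person_resid_sd = person_resid_sd,
    factor_resid_sd = factor_resid_sd,
    covariate_effects = covariate_effects,
    mortality_base = mortality_base,
    mortality_slope = mortality_slope,
    institution_base = institution_base,
    institution_slope = institution_slope,
    chronic_base = chronic_base, chronic_slope = chronic_slope,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  # slopes calibrated so that baseline latent health predicts the outcome
  # with a target discrimination (binormal AUC ~ 0.73 for mortality, the
  # usual order of magnitude for a broad health metric, and ~ 0.72 for
  # institutionalisation)
  sd_theta_total <- total_latent_sd(cfg)
  if (is.null(cfg$mortality_slope)) {
    cfg$mortality_slope <- solve_outcome_slope(0.73, sd_theta_total)
  }
  if (is.null(cfg$institution_slope)) {
    cfg$institution_slope <- solve_outcome_slope(0.72, sd_theta_total)
  }
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_persons >= 1, cfg$n_waves >= 2, cfg$n_items >= 1,
            cfg$n_first_order_factors >= 1)
  if (cfg$n_varying >= cfg$n_items) {
    stop("invalid config: number of wave-varying items (", cfg$n_varying,
         ") must be smaller than n_items (", cfg$n_items, ")")
  }
  if (any(cfg$categories_per_item < 2L)) {
    stop("invalid config: every item needs at least 2 categories")
  }
  if (cfg$mcar_rate < 0 || cfg$mcar_rate >= 1) {
    stop("invalid config: mcar_rate must lie in [0, 1)")
  }
  sds <- c(cfg$wave_drift_sd_b, cfg$wave_drift_sd_a, cfg$wave_effect_sd,
           cfg$factor_resid_sd)
  if (any(sds < 0)) stop("invalid config: standard deviations must be >= 0")
  if (cfg$person_resid_sd <= 0) {
    stop("invalid config: person_resid_sd must be > 0")
  }
  invisible(cfg)
}

#' Default covariate effects on latent ill-health
#'
#' Per-level linear effects of the generated covariates on the latent
#' ill-health trait (positive = worse health). Physical activity is the
#' dominant determinant, followed by age group, wealth, employment and
#' falls, mirroring the usual ordering of social determinants of health
#' in ageing cohorts. Effects are on the latent probit scale whose
#' person-wave residual SD defaults to 0.7.
#'
#' @return Named numeric vector.
#' @export
default_covariate_effects <- function() {
  c(activity   = -0.55,  # per level inactive -> moderately active -> active
    age_group  =  0.40,  # per level <65 -> 65-79 -> 80+
    wealth     = -0.12,  # per wealth quintile
    employment = -0.25,  # in work vs not
    falls      =  0.25,  # fall in last two years
    gender     =  0.10,  # female vs male
    education  = -0.10,  # some formal education vs none
    smoking    =  0.10,  # per level never -> former -> current
    drinking   = -0.15,  # per level none -> <= twice/week -> more
    social     = -0.05)  # per level small -> moderate -> large network
}

# between-person SD of baseline latent ill-health implied by the config
# (covariate spread + person-wave residual; the wave effect is shared by
# everyone at baseline and does not discriminate between persons);
# covariate variance uses the generator's marginals via their level
# variances
total_latent_sd <- function(cfg) {
  eff <- cfg$covariate_effects
  lv <- covariate_level_variances()
  common <- intersect(names(eff), names(lv))
  var_cov <- sum(eff[common]^2 * lv[common])
  sqrt(cfg$person_resid_sd^2 + var_cov)
}

# variances of the 0-based numeric level codes under the generator's
# marginal distributions (see sample_covariates)
covariate_level_variances <- function() {
  v_bern <- function(p) p * (1 - p)
  v_cat <- function(p) {
    x <- seq_along(p) - 1
    sum(p * x^2) - sum(p * x)^2
  }
  c(gender = v_bern(0.55), age_group = v_cat(c(0.5, 0.37, 0.13)),
    wealth = v_cat(rep(0.2, 5)), education = v_bern(0.65),
    activity = v_cat(c(0.25, 0.35, 0.40)), smoking = v_cat(c(0.45, 0.40, 0.15)),
    drinking = v_cat(c(0.30, 0.45, 0.25)), falls = v_bern(0.25),
    social = v_cat(c(0.35, 0.40, 0.25)), employment = v_bern(0.45))
}

#' Solve the outcome probit slope for a target AUC
#'
#' Under the generator's outcome model, outcome ~ Bernoulli(Phi(a0 +
#' a1 * theta)) with theta ~ Normal(0, sd^2), the discrimination of theta
#' for the outcome follows the binormal relation: augmenting the probit
#' with its latent normal errors makes (theta, outcome liability)
#' bivariate normal, giving AUC = Phi(a1 * sd / sqrt(2 * (1 + a1^2 *
#' sd^2) - ... )) in closed form only for balanced designs, so the slope
#' is solved numerically from the exact pair-probability integral.
#'
#' @param target_auc desired AUC of the latent trait for the outcome.
#' @param sd_theta marginal SD of the latent trait.
#' @return The positive slope achieving \code{target_auc}.
#' @export
solve_outcome_slope <- function(target_auc, sd_theta = 1) {
  stopifnot(target_auc > 0.5, target_auc < 1)
  f <- function(a1) binormal_auc(a1, sd_theta) - target_auc
  uniroot(f, c(1e-6, 50), tol = 1e-9)$root
}

# exact AUC of theta for a probit outcome with slope a1, by Gauss-Hermite
# quadrature over the case and control densities (pair-probability sum)
binormal_auc <- function(a1, sd_theta, n_nodes = 80) {
  gh <- gauss_hermite_probabilists(n_nodes)
  ord <- order(gh$nodes)
  x <- gh$nodes[ord] * sd_theta
  w <- gh$weights[ord]
  p <- pnorm(a1 * x)          # P(case | theta); intercept drops out of AUC
  f1 <- w * p / sum(w * p)
  f0 <- w * (1 - p) / sum(w * (1 - p))
  gt <- outer(x, x, ">") + 0.5 * outer(x, x, "==")
  drop(f1 %*% gt %*% f0)
}

# probabilists' Gauss-Hermite rule (weight exp(-x^2/2)/sqrt(2*pi)),
# from the Golub-Welsch eigen decomposition of the Jacobi matrix
gauss_hermite_probabilists <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}
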