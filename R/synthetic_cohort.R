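#' Sample person-level covariates
#'
#' Draws the covariate table for a synthetic cohort with simple
#' independent marginals (Bernoulli / multinomial). Categorical levels
#' are integer-coded from 0 so that the generator's linear covariate
#' effects apply per level step:
#' \describe{
#'   \item{gender}{0 male / 1 female (P(female) = 0.55)}
#'   \item{age_group}{0 = <65, 1 = 65-79, 2 = 80+}
#'   \item{wealth}{0..4, household wealth quintile, uniform}
#'   \item{education}{0 none / 1 some formal education}
#'   \item{activity}{0 inactive, 1 moderately active, 2 active}
#'   \item{smoking}{0 never, 1 former, 2 current}
#'   \item{drinking}{0 none, 1 <= twice a week, 2 more often}
#'   \item{falls}{0/1, any fall in the previous two years}
#'   \item{social}{0 small, 1 moderate, 2 large social network}
#'   \item{employment}{0 not in work / 1 in work}
#' }
#'
#' @param config a \code{\link{generator_config}}.
#' @return Data frame with \code{person_id} and the ten covariates.
#' @export
sample_covariates <- function(config) {
  set.seed(config$seed + 23L)
  n <- config$n_persons
  rcat <- function(p) sample.int(length(p), n, replace = TRUE, prob = p) - 1L
  data.frame(
    person_id = seq_len(n),
    gender = rbinom(n, 1, 0.55),
    age_group = rcat(c(0.50, 0.37, 0.13)),
    wealth = rcat(rep(0.2, 5)),
    education = rbinom(n, 1, 0.65),
    activity = rcat(c(0.25, 0.35, 0.40)),
    smoking = rcat(c(0.45, 0.40, 0.15)),
    drinking = rcat(c(0.30, 0.45, 0.25)),
    falls = rbinom(n, 1, 0.25),
    social = rcat(c(0.35, 0.40, 0.25)),
    employment = rbinom(n, 1, 0.45)
  )
}

#' Draw the generating (true) item and structural parameters
#'
#' Item slopes a_i are drawn positive and normalised to mean 1 (the same
#' identification used by the fitted model); thresholds b_ik are strictly
#' increasing, centred per item; wave offsets d_iw shift every threshold
#' of item i in wave w (d_i1 = 0, the first wave anchors the scale) and
#' wave slopes a_iw perturb a_i. Items unavailable in a wave keep
#' placeholder parameters that are never used.
#'
#' @param config a \code{\link{generator_config}}.
#' @param catalog an \code{\link{build_item_catalog}} result.
#' @return Object of class \code{"true_parameters"}: list with \code{a}
#'   (slopes), \code{b} (list of threshold vectors), \code{d}
#'   (items x waves threshold offsets), \code{a_w} (items x waves
#'   slopes), and \code{gamma} (covariate effects).
#' @export
sample_true_parameters <- function(config, catalog) {
  set.seed(config$seed + 37L)
  n_items <- config$n_items
  n_waves <- config$n_waves

  a <- exp(rnorm(n_items, 0, 0.35))
  a <- a / mean(a)                      # identification: mean slope = 1
  b <- lapply(seq_len(n_items), function(i) {
    K <- catalog$items$n_cat[i]
    # spread thresholds around the item's location; enforce gaps >= 0.3
    centre <- rnorm(1, 0, 0.5)
    gaps <- 0.3 + abs(rnorm(K - 1, 0.6, 0.25))
    th <- centre + cumsum(gaps)
    th - mean(th) + centre
  })

  d <- matrix(0, n_items, n_waves, dimnames = dimnames(catalog$availability))
  a_w <- matrix(a, n_items, n_waves, dimnames = dimnames(catalog$availability))
  if (n_waves >= 2) {
    d[, -1] <- rnorm(n_items * (n_waves - 1), 0, config$wave_drift_sd_b)
    if (config$wave_drift_sd_a > 0) {
      a_w[, -1] <- pmax(a_w[, -1] +
        rnorm(n_items * (n_waves - 1), 0, config$wave_drift_sd_a), 0.05)
    }
  }

  # person-level factor-specific residuals: shared by the items of a
  # first-order factor beyond the general trait (half weight on a
  # cross-loading item's secondary factor)
  lambda <- rep(config$factor_resid_sd, n_items)
  factor_scores <- matrix(rnorm(config$n_persons *
                                  config$n_first_order_factors),
                          config$n_persons, config$n_first_order_factors)

  structure(list(a = a, b = b, d = d, a_w = a_w, lambda = lambda,
                 factor_scores = factor_scores,
                 gamma = config$covariate_effects),
            class = "true_parameters")
}

#' Sample latent ill-health per person-wave
#'
#' Latent ill-health follows theta_pw = u_w + sum_c gamma_c x_pc + e_pw
#' with wave effect u_w ~ Normal(0, sigma_u^2) and person-wave residual
#' e_pw ~ Normal(0, sigma_theta^2). Covariates enter through their
#' 0-based integer level codes.
#'
#' @param config a \code{\link{generator_config}}.
#' @param covariates covariate table from \code{\link{sample_covariates}}
#'   (or any data frame whose effect-named columns are numeric codes).
#' @return Data frame \code{person_id, wave, theta} with attributes
#'   \code{u} (wave effects) and \code{xb} (per-person covariate
#'   contribution).
#' @export
sample_latent_health <- function(config, covariates = NULL) {
  if (is.null(covariates)) covariates <- sample_covariates(config)
  set.seed(config$seed + 51L)
  n <- config$n_persons
  W <- config$n_waves

  u <- rnorm(W, 0, config$wave_effect_sd)
  eff <- config$covariate_effects
  used <- intersect(names(eff), names(covariates))
  xb <- if (length(used)) {
    as.numeric(as.matrix(covariates[used]) %*% eff[used])
  } else {
    rep(0, n)
  }

  lat <- expand.grid(person_id = covariates$person_id, wave = seq_len(W),
                     KEEP.OUT.ATTRS = FALSE)
  lat <- lat[order(lat$person_id, lat$wave), , drop = FALSE]
  rownames(lat) <- NULL
  e <- rnorm(nrow(lat), 0, config$person_resid_sd)
  lat$theta <- u[lat$wave] + rep(xb, each = W) + e
  attr(lat, "u") <- u
  attr(lat, "xb") <- xb
  lat
}

#' Graded normal-ogive category probabilities
#'
#' P(X >= k) = Phi(a * theta - b_k) for k = 1..K-1, so
#' P(X = k) = Phi(a * theta - b_k) - Phi(a * theta - b_(k+1)) with the
#' conventions b_0 = -Inf and b_K = +Inf. Categories are 0-based.
#'
#' @param theta latent trait value(s).
#' @param a item slope.
#' @param b strictly increasing threshold vector (length K-1).
#' @return Matrix (length(theta) x K) of category probabilities, rows
#'   summing to 1.
#' @export
graded_probs <- function(theta, a, b) {
  if (is.unsorted(b, strictly = TRUE)) {
    stop("invalid parameters: thresholds must be strictly increasing")
  }
  upper <- cbind(1, pnorm(outer(theta, b, function(t, bb) a * t - bb)))
  probs <- upper - cbind(upper[, -1, drop = FALSE], 0)
  colnames(probs) <- paste0("cat", seq_len(length(b) + 1) - 1)
  probs
}

#' Sample ordinal item responses from the graded normal-ogive model
#'
#' Draws responses by inverse-CDF sampling of the category probabilities
#' under the wave-specific item parameters (slope a_iw, thresholds
#' b_ik + d_iw). When the generating parameters carry factor-specific
#' person residuals (\code{lambda}, \code{factor_scores}), the item
#' liability is a_iw * theta_pw + lambda_i * F_p,f(i) (+ half-weight
#' secondary factor for cross-loading items), which induces the
#' first-order factor structure on top of the general trait. Cells for
#' items not administered in a wave are emitted as structurally missing.
#'
#' @param latent latent table from \code{\link{sample_latent_health}}.
#' @param catalog item catalog.
#' @param true_params \code{\link{sample_true_parameters}} result.
#' @param seed integer seed.
#' @return A \code{"response_panel"}: long data frame
#'   \code{person_id, wave, item_id, response, status} with status
#'   \code{"observed"} or \code{"structural"}; responses are 0-based,
#'   \code{NA} when not observed.
#' @export
sample_item_responses <- function(latent, catalog, true_params, seed = 1L) {
  set.seed(seed + 77L)
  items <- catalog$items
  n_pw <- nrow(latent)
  out <- vector("list", nrow(items))

  for (i in seq_len(nrow(items))) {
    b_i <- true_params$b[[i]]
    if (is.unsorted(b_i, strictly = TRUE)) {
      stop("invalid parameters: thresholds of ", items$item_id[i],
           " are not strictly increasing")
    }
    resp <- rep(NA_integer_, n_pw)
    status <- rep("structural", n_pw)
    # factor-specific liability component, constant over waves
    fac <- rep(0, n_pw)
    if (!is.null(true_params$lambda) && true_params$lambda[i] > 0) {
      F <- true_params$factor_scores
      f1 <- catalog$items$factor[i]
      pidx <- match(latent$person_id, seq_len(nrow(F)))
      fac <- true_params$lambda[i] * F[pidx, f1]
      f2 <- catalog$items$factor2[i]
      if (!is.na(f2)) fac <- fac + 0.5 * true_params$lambda[i] * F[pidx, f2]
    }
    for (w in seq_len(ncol(catalog$availability))) {
      idx <- which(latent$wave == w)
      if (!catalog$availability[i, w] || !length(idx)) next
      liab <- true_params$a_w[i, w] * latent$theta[idx] + fac[idx]
      bw <- b_i + true_params$d[i, w]
      ge <- cbind(1, pnorm(outer(liab, bw, "-")))   # P(X >= k)
      p <- ge - cbind(ge[, -1, drop = FALSE], 0)
      cum <- t(apply(p, 1, cumsum))
      u <- runif(length(idx))
      resp[idx] <- rowSums(u > cum)    # 0-based category index
      status[idx] <- "observed"
    }
    out[[i]] <- data.frame(person_id = latent$person_id, wave = latent$wave,
                           item_id = items$item_id[i], response = resp,
                           status = status, stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, out)
  panel <- panel[order(panel$person_id, panel$wave, panel$item_id), ]
  rownames(panel) <- NULL
  class(panel) <- c("response_panel", "data.frame")
  panel
}

#' Apply MCAR missingness to a response panel
#'
#' Each observed cell is independently set missing with probability
#' \code{mcar_rate} (status \code{"mcar"}); structurally missing cells
#' (items not administered in a wave) are left as-is and stay flagged
#' \code{"structural"}.
#'
#' @param panel a \code{"response_panel"}.
#' @param catalog item catalog (used only for validation).
#' @param mcar_rate probability in [0, 1).
#' @param seed integer seed.
#' @return The panel with missing cells blanked and status updated.
#' @export
apply_missingness <- function(panel, catalog, mcar_rate, seed = 1L) {
  stopifnot(mcar_rate >= 0, mcar_rate < 1)
  if (mcar_rate == 0) return(panel)
  set.seed(seed + 101L)
  obs <- which(panel$status == "observed")
  hit <- obs[runif(length(obs)) < mcar_rate]
  panel$response[hit] <- NA_integer_
  panel$status[hit] <- "mcar"
  panel
}

#' Sample mortality, institutionalisation and chronic-condition outcomes
#'
#' Outcomes are probit-linked to \emph{baseline} (wave 1) latent
#' ill-health: mortality ~ Bernoulli(Phi(alpha0 + alpha1 * theta_p1))
#' with alpha1 > 0 (worse health raises mortality), institutionalisation
#' analogously with a smaller base rate, and each of the eight chronic
#' conditions through its own probit with a positive slope.
#'
#' @param latent latent table from \code{\link{sample_latent_health}}.
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed.
#' @return Data frame \code{person_id, mortality, institution,
#'   cond1..cond8}.
#' @export
sample_outcomes <- function(latent, config, seed = 1L) {
  set.seed(seed + 131L)
  base <- latent[latent$wave == 1L, ]
  theta0 <- base$theta
  n <- nrow(base)

  # intercepts place the base rate at theta = 0 (average latent health)
  mort <- rbinom(n, 1, pnorm(qnorm(config$mortality_base) +
                               config$mortality_slope * theta0))
  inst <- rbinom(n, 1, pnorm(qnorm(config$institution_base) +
                               config$institution_slope * theta0))
  conds <- sapply(seq_len(8), function(j) {
    rbinom(n, 1, pnorm(qnorm(config$chronic_base[j]) +
                         config$chronic_slope[j] * theta0))
  })
  colnames(conds) <- paste0("cond", 1:8)
  cbind(data.frame(person_id = base$person_id, mortality = mort,
                   institution = inst), as.data.frame(conds))
}

#' Generate a complete synthetic cohort
#'
#' Composes catalog construction, covariate sampling, latent-trait
#' simulation, graded response sampling, MCAR missingness and outcome
#' generation into one seeded, reproducible object with the generating
#' parameters retained for recovery tests.
#'
#' @param config a \code{\link{generator_config}}.
#' @return Object of class \code{"synthetic_cohort"}: list with
#'   \code{panel}, \code{catalog}, \code{covariates}, \code{outcomes},
#'   \code{latent}, \code{true_parameters} and \code{config}.
#' @examples
#' coh <- generate_cohort(generator_config(n_persons = 30, n_items = 10))
#' nrow(coh$panel) == 30 * 6 * 10
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  catalog <- build_item_catalog(config)
  covariates <- sample_covariates(config)
  true_params <- sample_true_parameters(config, catalog)
  latent <- sample_latent_health(config, covariates)
  panel <- sample_item_responses(latent, catalog, true_params,
                                 seed = config$seed)
  panel <- apply_missingness(panel, catalog, config$mcar_rate,
                             seed = config$seed)
  outcomes <- sample_outcomes(latent, config, seed = config$seed)
  structure(list(panel = panel, catalog = catalog, covariates = covariates,
                 outcomes = outcomes, latent = latent,
                 true_parameters = true_params, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_persons, "persons,",
      x$config$n_waves, "waves,", x$config$n_items, "items\n")
  tab <- table(x$panel$status)
  cat("Cells:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
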