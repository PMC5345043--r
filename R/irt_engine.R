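#' Specification of a Bayesian multilevel graded-ogive IRT fit
#'
#' @param variance_config one of \code{"M1_none"} (no wave variation of
#'   item parameters), \code{"M2_itemwise_intercept"} (per-item variance
#'   of wave threshold offsets), \code{"M3_homogeneous_intercept"}
#'   (shared offset variance) or \code{"M4_hierarchical_full"} (itemwise
#'   intercept and slope variances with hierarchical item and slope
#'   parameters).
#' @param n_iter total MCMC iterations (default 5000).
#' @param burn_in burn-in iterations (default 100; extended automatically
#'   when the Geweke diagnostic on the variance chains fails, with a
#'   warning).
#' @param thin thinning interval for retained draws.
#' @param dev_every evaluate the deviance on every \code{dev_every}-th
#'   retained draw (the DIC average is over this subset).
#' @param seed integer seed for the chain.
#' @param prior list overriding prior hyperparameters: \code{a_mean},
#'   \code{a_var} (slope normal prior, truncated > 0), \code{b_mean},
#'   \code{b_var} (threshold normal prior), \code{ig_shape},
#'   \code{ig_scale} (inverse-gamma for every variance),
#'   \code{hyper_var} (variance of the M4 hyper-mean priors).
#' @param fix_items optional list \code{list(a = ..., b = list(...))}
#'   fixing the item parameters (used for oracle checks; disables the
#'   identification rescaling).
#' @param fix_sigma_u,fix_sigma_theta optional fixed values for the wave
#'   and residual SDs.
#' @param keep_theta_draws retain the full ability chain (memory-heavy;
#'   default FALSE keeps running mean/SD only).
#' @param rescale apply the mean-slope-one identification rescaling after
#'   every sweep (default TRUE).
#' @return Object of class \code{"mlirt_spec"}.
#' @export
mlirt_spec <- function(variance_config = c("M4_hierarchical_full",
                                           "M1_none",
                                           "M2_itemwise_intercept",
                                           "M3_homogeneous_intercept"),
                       n_iter = 5000L, burn_in = 100L, thin = 1L,
                       dev_every = 5L, seed = 1L,
                       prior = list(), fix_items = NULL,
                       fix_sigma_u = NULL, fix_sigma_theta = NULL,
                       keep_theta_draws = FALSE, rescale = TRUE) {
  variance_config <- match.arg(variance_config)
  stopifnot(burn_in < n_iter, thin >= 1)
  pr <- utils::modifyList(
    list(a_mean = 1, a_var = 2, b_mean = 0, b_var = 4,
         ig_shape = 1, ig_scale = 1, hyper_var = 10),
    prior)
  if (any(unlist(pr[c("a_var", "b_var", "hyper_var")]) <= 0)) {
    stop("prior variances must be positive")
  }
  structure(list(variance_config = variance_config,
                 model_id = match(variance_config,
                                  c("M1_none", "M2_itemwise_intercept",
                                    "M3_homogeneous_intercept",
                                    "M4_hierarchical_full")),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), dev_every = as.integer(dev_every),
                 seed = as.integer(seed), prior = pr,
                 fix_items = fix_items,
                 fix_sigma_u = fix_sigma_u,
                 fix_sigma_theta = fix_sigma_theta,
                 keep_theta_draws = keep_theta_draws,
                 rescale = rescale),
            class = "mlirt_spec")
}

# internal: index a long panel for the C++ sampler (0-based indices,
# observations sorted by person-wave)
index_panel <- function(panel, catalog) {
  obs <- panel[!is.na(panel$response), , drop = FALSE]
  if (!nrow(obs)) stop("panel has no observed responses")
  item_ids <- catalog$items$item_id
  n_items <- length(item_ids)
  n_waves <- ncol(catalog$availability)

  item_idx <- match(obs$item_id, item_ids)
  if (anyNA(item_idx)) stop("panel contains items missing from the catalog")
  pw_key <- paste(obs$person_id, obs$wave)
  pw_levels <- unique(pw_key[order(obs$person_id, obs$wave)])
  pw_idx <- match(pw_key, pw_levels)

  ord <- order(pw_idx)
  obs <- obs[ord, ]
  item_idx <- item_idx[ord]
  pw_idx <- pw_idx[ord]
  n_pw <- length(pw_levels)

  pw_tab <- do.call(rbind, strsplit(pw_levels, " "))
  pw_person <- as.integer(pw_tab[, 1])
  pw_wave <- as.integer(pw_tab[, 2])

  K <- catalog$items$n_cat
  # per-item data category counts must reach at least 2
  for (i in unique(item_idx)) {
    n_seen <- length(unique(obs$response[item_idx == i]))
    if (n_seen < 2) {
      stop("item ", item_ids[i], " is observed with fewer than 2 categories")
    }
  }
  if (any(obs$response < 0 | obs$response >= K[item_idx])) {
    stop("responses outside the catalogued category range")
  }

  obs_wave0 <- obs$wave - 1L
  iw <- (item_idx - 1L) * n_waves + obs_wave0
  iw_ord <- order(iw)
  iw_starts <- c(0L, cumsum(tabulate(iw + 1L, nbins = n_items * n_waves)))

  cat_offsets <- c(0L, cumsum(K))
  catk <- cat_offsets[item_idx] + obs$response
  cat_ord <- order(catk)
  cat_starts <- c(0L, cumsum(tabulate(catk + 1L, nbins = sum(K))))

  thr_offsets <- c(0L, cumsum(K - 1L))
  pw_starts <- c(0L, cumsum(tabulate(pw_idx, nbins = n_pw)))

  list(obs_pw = pw_idx - 1L, obs_item = item_idx - 1L,
       obs_wave = obs_wave0, obs_x = as.integer(obs$response),
       n_pw = n_pw, n_items = n_items, n_waves = n_waves,
       K = as.integer(K), pw_person = pw_person, pw_wave0 = pw_wave - 1L,
       pw_starts = as.integer(pw_starts),
       iw_order = as.integer(iw_ord - 1L), iw_starts = as.integer(iw_starts),
       cat_order = as.integer(cat_ord - 1L),
       cat_starts = as.integer(cat_starts),
       cat_offsets = as.integer(cat_offsets),
       thr_offsets = as.integer(thr_offsets))
}

#' Fit the Bayesian multilevel graded normal-ogive IRT model
#'
#' Measurement model: P(X_pwi >= k | theta_pw) = Phi(a_iw * theta_pw -
#' b_iwk) with ability decomposed as theta_pw = u_w + e_pw, u_w ~
#' Normal(0, sigma_u^2), e_pw ~ Normal(0, sigma_theta^2). The latent
#' trait is ill-health (higher = worse), aligned with the item coding.
#' Wave-varying items simply contribute no observations in the waves
#' where they are not administered; the anchor items carry the common
#' scale across waves. Missing cells are skipped (missing at random).
#' Parameters are sampled jointly by Gibbs with truncated-normal data
#' augmentation and a Metropolis step for the ordered thresholds; after
#' every sweep the scale is identified by setting the mean item slope to
#' one. Persons have no random effect inside the measurement model;
#' longitudinal dependence between a person's waves is handled
#' downstream by the mixed model.
#'
#' @param panel a \code{"response_panel"} (already passed through
#'   \code{\link{filter_personwave_irt}}).
#' @param catalog matching \code{"item_catalog"}.
#' @param spec an \code{\link{mlirt_spec}}.
#' @return Object of class \code{"irt_posterior"}: retained draws of the
#'   item slopes, thresholds, wave effects and variances, per-person-wave
#'   EAP mean/SD of ability, posterior means of the wave-level item
#'   parameters, deviance draws, and Metropolis diagnostics.
#' @export
fit_mlirt <- function(panel, catalog, spec = mlirt_spec()) {
  stopifnot(inherits(spec, "mlirt_spec"))
  idx <- index_panel(panel, catalog)

  # every wave must carry at least one anchor observation for linking
  cls <- classify_items(catalog)
  anchor_idx <- match(cls$anchor_set, catalog$items$item_id) - 1L
  for (w in sort(unique(idx$obs_wave))) {
    if (!any(idx$obs_item[idx$obs_wave == w] %in% anchor_idx)) {
      stop("wave ", w + 1L, " has no observed anchor items: not linkable")
    }
  }

  control <- list(
    fix_items = !is.null(spec$fix_items),
    rescale = spec$rescale,
    fix_su2 = if (is.null(spec$fix_sigma_u)) -1 else spec$fix_sigma_u^2,
    fix_st2 = if (is.null(spec$fix_sigma_theta)) -1 else spec$fix_sigma_theta^2,
    keep_theta = spec$keep_theta_draws)
  if (control$fix_items) {
    control$a_fix <- spec$fix_items$a
    control$thr_fix <- unlist(spec$fix_items$b)
  }

  set.seed(spec$seed)
  raw <- mlirt_gibbs_cpp(idx$obs_pw, idx$obs_item, idx$obs_wave, idx$obs_x,
                         idx$n_pw, idx$n_items, idx$n_waves,
                         idx$K, idx$pw_wave0, idx$pw_starts,
                         idx$iw_order, idx$iw_starts,
                         idx$cat_order, idx$cat_starts, idx$cat_offsets,
                         idx$thr_offsets,
                         spec$model_id, spec$n_iter, spec$burn_in,
                         spec$thin, spec$dev_every, spec$prior, control)

  post <- structure(list(
    spec = spec, catalog = catalog,
    n_pw = idx$n_pw, n_items = idx$n_items, n_waves = idx$n_waves,
    person_id = idx$pw_person, wave = idx$pw_wave0 + 1L,
    draws = list(a = raw$a, b = raw$b, u = raw$u,
                 sigma_u2 = raw$sigma_u2, sigma_theta2 = raw$sigma_theta2,
                 icc = raw$icc, deviance = raw$deviance,
                 theta = if (spec$keep_theta_draws) raw$theta_draws),
    theta_mean = raw$theta_mean, theta_sd = raw$theta_sd,
    d_mean = matrix(raw$d_mean, idx$n_items, idx$n_waves, byrow = TRUE),
    aw_mean = matrix(raw$aw_mean, idx$n_items, idx$n_waves, byrow = TRUE),
    thr_offsets = idx$thr_offsets,
    mh_acceptance = raw$mh_acceptance,
    index = idx), class = "irt_posterior")

  # convergence screen on the variance chains; on failure treat the first
  # half of the retained draws as extra burn-in
  if (is.null(spec$fix_sigma_u) || is.null(spec$fix_sigma_theta)) {
    z <- suppressWarnings(c(geweke_z(raw$sigma_theta2),
                            geweke_z(raw$sigma_u2)))
    if (any(abs(z) > 3, na.rm = TRUE)) {
      warning("Geweke diagnostic failed (|z| = ",
              sprintf("%.1f", max(abs(z), na.rm = TRUE)),
              "); discarding the first half of retained draws as ",
              "additional burn-in")
      post <- drop_burnin(post, 0.5)
    }
  }
  post
}

# Geweke convergence z-score: compare means of the first 10% and last 50%
# of a chain, SEs from batch means
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 40) return(NA_real_)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[seq.int(n - floor(frac2 * n) + 1, n)]
  se_bm <- function(v) {
    b <- max(2, floor(sqrt(length(v))))
    nb <- floor(length(v) / b)
    bm <- colMeans(matrix(v[seq_len(nb * b)], b, nb))
    sd(bm) / sqrt(nb)
  }
  (mean(x1) - mean(x2)) / sqrt(se_bm(x1)^2 + se_bm(x2)^2)
}

# discard the first `frac` of retained draws (post-hoc burn-in extension)
drop_burnin <- function(post, frac = 0.5) {
  n <- length(post$draws$sigma_u2)
  keep <- seq.int(floor(frac * n) + 1L, n)
  for (nm in c("a", "b", "u")) {
    post$draws[[nm]] <- post$draws[[nm]][keep, , drop = FALSE]
  }
  for (nm in c("sigma_u2", "sigma_theta2", "icc")) {
    post$draws[[nm]] <- post$draws[[nm]][keep]
  }
  if (!is.null(post$draws$theta)) {
    post$draws$theta <- post$draws$theta[keep, , drop = FALSE]
    post$theta_mean <- colMeans(post$draws$theta)
    post$theta_sd <- apply(post$draws$theta, 2, sd)
  }
  nd <- length(post$draws$deviance)
  if (nd > 1) {
    post$draws$deviance <- post$draws$deviance[seq.int(floor(frac * nd) + 1L, nd)]
  }
  post
}

#' @export
print.irt_posterior <- function(x, ...) {
  cat("Multilevel graded-ogive IRT posterior (",
      x$spec$variance_config, ")\n", sep = "")
  cat(" ", x$n_pw, "person-waves,", x$n_items, "items,",
      length(x$draws$sigma_u2), "retained draws\n")
  cat("  EAP reliability:", round(eap_reliability(x), 3),
      " wave ICC:", round(wave_icc(x)$icc, 3), "\n")
  invisible(x)
}

#' Expected-a-posteriori ability estimates
#'
#' @param posterior an \code{"irt_posterior"}.
#' @return Data frame \code{person_id, wave, theta_eap, theta_psd}: the
#'   posterior mean and SD of ability per person-wave over the retained
#'   draws.
#' @export
eap_scores <- function(posterior) {
  data.frame(person_id = posterior$person_id, wave = posterior$wave,
             theta_eap = posterior$theta_mean,
             theta_psd = posterior$theta_sd)
}

#' EAP reliability of the latent trait
#'
#' rel = Var(EAP) / (Var(EAP) + mean(posterior SD^2)) over person-waves:
#' the share of total ability variance captured by the point estimates.
#'
#' @param posterior an \code{"irt_posterior"}.
#' @return Scalar in [0, 1].
#' @export
eap_reliability <- function(posterior) {
  v <- var(posterior$theta_mean)
  v / (v + mean(posterior$theta_sd^2))
}

#' Deviance information criterion of an IRT fit
#'
#' D(par) = -2 * sum of observed-cell log category probabilities; Dbar is
#' the average over (a subset of) retained draws, pD = Dbar - D(posterior
#' means), DIC = Dbar + pD. Lower is better.
#'
#' @param posterior an \code{"irt_posterior"}.
#' @return List with \code{DIC}, \code{pD} and \code{Dbar}.
#' @export
dic <- function(posterior) {
  idx <- posterior$index
  dbar <- mean(posterior$draws$deviance)
  # deviance at posterior means of a_iw, b, d, theta
  b_hat <- colMeans(posterior$draws$b)
  theta <- posterior$theta_mean
  ll <- 0
  for (i in seq_len(posterior$n_items)) {
    sel <- idx$obs_item == i - 1L
    if (!any(sel)) next
    K <- idx$K[i]
    thr <- b_hat[(idx$thr_offsets[i] + 1):idx$thr_offsets[i + 1]]
    w <- idx$obs_wave[sel] + 1L
    mu <- posterior$aw_mean[i, w] * theta[idx$obs_pw[sel] + 1L] -
      posterior$d_mean[i, w]
    upper <- cbind(1, pnorm(outer(mu, thr, "-")))
    probs <- upper - cbind(upper[, -1, drop = FALSE], 0)
    p <- probs[cbind(seq_along(mu), idx$obs_x[sel] + 1L)]
    ll <- ll + sum(log(pmax(p, 1e-300)))
  }
  dhat <- -2 * ll
  pd <- dbar - dhat
  list(DIC = dbar + pd, pD = pd, Dbar = dbar)
}

#' Wave-level intraclass correlation of ability
#'
#' Per retained draw, icc = sigma_u^2 / (sigma_u^2 + sigma_theta^2): the
#' share of ability variance attributable to waves. Point estimate is
#' the posterior median; the interval the central 95% of draws.
#'
#' @param posterior an \code{"irt_posterior"}.
#' @return List with \code{icc} and \code{ci} (length-2 vector).
#' @export
wave_icc <- function(posterior) {
  draws <- posterior$draws$icc
  list(icc = median(draws),
       ci = unname(quantile(draws, c(0.025, 0.975))))
}

#' Compare fitted multilevel IRT models
#'
#' Ranks candidate fits by EAP reliability (higher better) and DIC
#' (lower better). Because EAP reliability is itself a Monte-Carlo
#' estimate, differences smaller than \code{rel_tol} are treated as
#' ties: the selected model has reliability within \code{rel_tol} of the
#' maximum and, among those, the lowest DIC. When the two criteria
#' genuinely disagree on the top model (beyond the tolerance) the
#' disagreement is flagged and reported rather than silently resolved.
#'
#' @param fits named list of \code{"irt_posterior"} objects.
#' @param rel_tol reliability equivalence margin (default 0.02, about
#'   the Monte-Carlo noise of the reliability estimate at typical chain
#'   lengths).
#' @return List with a \code{table} (model, reliability, DIC, pD),
#'   \code{selected} (name), and \code{criteria_agree} flag.
#' @export
compare_models <- function(fits, rel_tol = 0.02) {
  stopifnot(length(fits) >= 1)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  rel <- vapply(fits, eap_reliability, numeric(1))
  dics <- lapply(fits, dic)
  dic_v <- vapply(dics, `[[`, numeric(1), "DIC")
  tab <- data.frame(model = nm, eap_reliability = rel, DIC = dic_v,
                    pD = vapply(dics, `[[`, numeric(1), "pD"),
                    row.names = NULL)
  near_best <- which(rel >= max(rel) - rel_tol)
  sel <- near_best[which.min(dic_v[near_best])]
  agree <- (which.max(rel) == which.min(dic_v))
  if (!agree) {
    message("model comparison: EAP reliability favours ", nm[which.max(rel)],
            " but DIC favours ", nm[which.min(dic_v)])
  }
  list(table = tab, selected = nm[sel], criteria_agree = agree)
}

#' Transform EAP ability to the 0-100 health score
#'
#' Because the latent trait measures ill-health, the transform reverses
#' the sign: score = 100 * (theta_max - theta) / (theta_max - theta_min)
#' with the pooled min/max over all person-waves, so the worst observed
#' ability maps to 0 and the best to 100 and higher scores mean better
#' health. The transform parameters are stored for out-of-sample use;
#' new abilities outside the stored range are clamped to [0, 100] with a
#' warning.
#'
#' @param eap_table data frame from \code{\link{eap_scores}}.
#' @param transform optional stored transform (list with
#'   \code{theta_min}, \code{theta_max}) for out-of-sample application.
#' @return A \code{"health_score_panel"} data frame: \code{person_id,
#'   wave, score, score_psd} with a \code{"transform"} attribute.
#' @export
to_health_score <- function(eap_table, transform = NULL) {
  if (is.null(transform)) {
    transform <- list(theta_min = min(eap_table$theta_eap),
                      theta_max = max(eap_table$theta_eap))
  }
  rng <- transform$theta_max - transform$theta_min
  if (rng <= 0) stop("degenerate ability range: theta_max equals theta_min")
  score <- 100 * (transform$theta_max - eap_table$theta_eap) / rng
  if (any(score < -1e-8 | score > 100 + 1e-8)) {
    warning("abilities outside the stored range; scores clamped to [0, 100]")
  }
  score <- pmin(pmax(score, 0), 100)
  out <- data.frame(person_id = eap_table$person_id, wave = eap_table$wave,
                    score = score,
                    score_psd = 100 * eap_table$theta_psd / rng)
  attr(out, "transform") <- transform
  class(out) <- c("health_score_panel", "data.frame")
  out
}

#' Correlation between the health score and a simple sum score
#'
#' Pearson correlation (absolute value) between the 0-100 health score
#' and the per-person-wave mean of the observed recoded item responses
#' (mean rather than sum, so item availability differences across waves
#' do not distort the comparison).
#'
#' @param scores a \code{"health_score_panel"}.
#' @param panel the \code{"response_panel"} the scores were computed
#'   from.
#' @return Absolute Pearson correlation.
#' @export
sumscore_correlation <- function(scores, panel) {
  obs <- panel[!is.na(panel$response), ]
  ss <- aggregate(response ~ person_id + wave, data = obs, FUN = mean)
  m <- merge(scores, ss, by = c("person_id", "wave"))
  abs(cor(m$score, m$response))
}
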