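#' Crossed random-intercept mixed model for the health score
#'
#' Fits y = X beta + alpha_person + gamma_wave + epsilon with
#' independent normal random intercepts for persons and waves (crossed,
#' not nested), by maximum likelihood (so the likelihood-ratio test
#' against the ordinary linear model and the AIC are coherent).
#' Estimation is delegated to \code{lme4::lmer}.
#'
#' @param y numeric response (health score per person-wave).
#' @param X design matrix or data frame of fixed covariates (no
#'   intercept column; one is added).
#' @param person_ids,wave_ids grouping vectors, same length as y.
#' @return Object of class \code{"mixed_model_fit"}: list with
#'   \code{coefficients} (data frame: estimate, se, z, ci_lower,
#'   ci_upper, p), \code{sd_person}, \code{sd_wave}, \code{sd_resid},
#'   \code{loglik}, \code{AIC}, \code{n_obs}, \code{n_persons},
#'   \code{n_par} and the underlying \code{lme4} fit.
#' @export
fit_lmm <- function(y, X, person_ids, wave_ids) {
  X <- as.data.frame(X)
  mm <- stats::model.matrix(~ ., data = X)
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrx$pivot[seq.int(qrx$rank + 1, ncol(mm))]]
    stop("rank-deficient design: aliased column(s) ",
         paste(aliased, collapse = ", "))
  }
  dat <- data.frame(.y = y, X, .person = factor(person_ids),
                    .wave = factor(wave_ids))
  fml <- as.formula(paste(".y ~", paste(colnames(X), collapse = " + "),
                          "+ (1 | .person) + (1 | .wave)"))
  fit <- lme4::lmer(fml, data = dat, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_person <- vc$sdcor[vc$grp == ".person"]
  sd_wave <- vc$sdcor[vc$grp == ".wave"]
  sd_resid <- vc$sdcor[vc$grp == "Residual"]
  if (min(sd_person, sd_wave) < 1e-8) {
    message("a random-effect variance was estimated at the boundary (0)")
  }

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z),
                      ci_lower = unname(beta - qnorm(0.975) * se),
                      ci_upper = unname(beta + qnorm(0.975) * se),
                      p = unname(2 * pnorm(-abs(z))), row.names = NULL)
  ll <- as.numeric(logLik(fit))
  n_par <- length(beta) + 3L      # fixed effects + 2 RE variances + residual
  structure(list(coefficients = coefs, sd_person = sd_person,
                 sd_wave = sd_wave, sd_resid = sd_resid,
                 loglik = ll, AIC = -2 * ll + 2 * n_par,
                 n_obs = length(y),
                 n_persons = length(unique(person_ids)),
                 n_par = n_par, lme4_fit = fit),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("Crossed random-intercept mixed model (ML):",
      x$n_obs, "obs,", x$n_persons, "persons\n")
  cat(sprintf("  SD person %.2f | SD wave %.2f | SD resid %.2f | ICC %.2f\n",
              x$sd_person, x$sd_wave, x$sd_resid, conditional_icc(x)))
  print(x$coefficients, digits = 3)
  invisible(x)
}

# log-likelihood and parameter count from the objects this package uses
loglik_k <- function(fit) {
  if (inherits(fit, "mixed_model_fit")) {
    list(ll = fit$loglik, k = fit$n_par)
  } else if (inherits(fit, "lm")) {
    list(ll = as.numeric(logLik(fit)), k = attr(logLik(fit), "df"))
  } else if (is.list(fit) && !is.null(fit$loglik)) {
    list(ll = fit$loglik, k = if (is.null(fit$k)) fit$n_par else fit$k)
  } else {
    stop("cannot extract a log-likelihood from this object")
  }
}

#' Likelihood-ratio test of the mixed model against the linear model
#'
#' chi2 = 2 (loglik_mixed - loglik_ols) referred to a chi-square with 2
#' degrees of freedom (the two random-intercept variances). Because the
#' null places both variances on the boundary of the parameter space the
#' naive chi2_2 reference is conservative; it is used as-is to match
#' standard reporting practice.
#'
#' @param mixed_fit a \code{"mixed_model_fit"}.
#' @param ols_fit an \code{lm} fit of the same fixed part.
#' @return List with \code{chisq}, \code{df} (= 2) and \code{p}.
#' @export
lrt_vs_linear <- function(mixed_fit, ols_fit) {
  ll1 <- loglik_k(mixed_fit)$ll
  ll0 <- loglik_k(ols_fit)$ll
  chisq <- max(2 * (ll1 - ll0), 0)
  list(chisq = chisq, df = 2L, p = pchisq(chisq, df = 2, lower.tail = FALSE))
}

#' Adjusted McFadden pseudo R-squared
#'
#' 1 - (loglik_full - k_full) / loglik_null, where k_full is the number
#' of estimated parameters of the full model; the penalty guards against
#' mechanical gains from added parameters.
#'
#' @param full_fit,null_fit fitted models (\code{"mixed_model_fit"},
#'   \code{lm}, or a list with \code{loglik} and \code{k}).
#' @return Scalar pseudo R-squared.
#' @export
mcfadden_adjusted <- function(full_fit, null_fit) {
  f <- loglik_k(full_fit)
  n <- loglik_k(null_fit)
  1 - (f$ll - f$k) / n$ll
}

#' Conditional intraclass correlation of a mixed model
#'
#' (sigma_person^2 + sigma_wave^2) / (sigma_person^2 + sigma_wave^2 +
#' sigma_resid^2): the share of score variance attributable to the
#' random effects.
#'
#' @param fit a \code{"mixed_model_fit"}, or a list/vector with elements
#'   \code{sd_person}, \code{sd_wave}, \code{sd_resid}.
#' @return Scalar in [0, 1].
#' @export
conditional_icc <- function(fit) {
  v <- c(fit$sd_person, fit$sd_wave, fit$sd_resid)^2
  (v[1] + v[2]) / sum(v)
}

#' Multiple linear regression with standardized coefficient magnitudes
#'
#' Ordinary least squares of y on X, reporting unstandardized
#' coefficients with 95% confidence intervals and p-values plus the
#' absolute standardized coefficients |beta_std| = |coef| * SD(x) /
#' SD(y).
#'
#' @param y numeric response.
#' @param X data frame or matrix of predictors.
#' @return List with \code{table} (term, estimate, ci_lower, ci_upper,
#'   p, beta_std) and the underlying \code{lm} fit.
#' @export
ols_standardized <- function(y, X) {
  X <- as.data.frame(X)
  dat <- data.frame(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  ci <- confint(fit)
  mm <- stats::model.matrix(fit)
  sdx <- apply(mm, 2, sd)
  beta_std <- abs(coef(fit)) * sdx / sd(y)
  beta_std["(Intercept)"] <- NA
  list(table = data.frame(term = rownames(sm), estimate = sm[, 1],
                          ci_lower = ci[, 1], ci_upper = ci[, 2],
                          p = sm[, 4], beta_std = unname(beta_std),
                          row.names = NULL),
       lm_fit = fit)
}

# DeLong placement values for one marker: for each case, the fraction of
# controls it exceeds (ties half); and symmetrically for controls
delong_placements <- function(marker, outcome) {
  x <- marker[outcome == 1]
  y <- marker[outcome == 0]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi),
       m = m, n = n)
}

#' Empirical AUC with DeLong confidence interval
#'
#' Mann-Whitney AUC (ties counted one half) of the health score for an
#' adverse binary outcome, oriented so that a \emph{lower} score
#' predicts the outcome (the AUC of the negated score). The 95%
#' confidence interval uses the DeLong placement-value variance.
#'
#' @param score numeric health score (higher = better health).
#' @param outcome binary vector (1 = event).
#' @param orientation \code{"lower_predicts_event"} (default, used for
#'   the health score) or \code{"higher_predicts_event"} (e.g. for a
#'   chronic-condition count).
#' @return Object of class \code{"auc_result"}: list with \code{auc},
#'   \code{ci}, \code{var}, \code{method}.
#' @export
auc_empirical <- function(score, outcome,
                          orientation = c("lower_predicts_event",
                                          "higher_predicts_event")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(score) & !is.na(outcome)
  score <- score[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2) {
    stop("outcome must contain both classes")
  }
  marker <- if (orientation == "lower_predicts_event") -score else score
  pl <- delong_placements(marker, outcome)
  v <- var(pl$v10) / pl$m + var(pl$v01) / pl$n
  ci <- pmin(pmax(pl$auc + c(-1, 1) * qnorm(0.975) * sqrt(v), 0), 1)
  structure(list(auc = pl$auc, ci = ci, var = v, method = "pooled"),
            class = "auc_result")
}

#' Gender-adjusted AUC (stratum-weighted DeLong)
#'
#' Covariate adjustment by stratification: the adjusted AUC is the
#' weighted average of within-gender AUCs with weights proportional to
#' the within-stratum number of case-control pairs; its variance is the
#' corresponding weighted combination of the stratified DeLong
#' variances. Strata missing either outcome class are excluded with a
#' warning.
#'
#' @inheritParams auc_empirical
#' @param gender stratification vector.
#' @return An \code{"auc_result"} with method \code{"gender_adjusted"}.
#' @export
auc_gender_adjusted <- function(score, outcome, gender,
                                orientation = c("lower_predicts_event",
                                                "higher_predicts_event")) {
  orientation <- match.arg(orientation)
  strata <- split(seq_along(score), gender)
  res <- list(); w <- numeric()
  for (g in names(strata)) {
    idx <- strata[[g]]
    if (length(unique(na.omit(outcome[idx]))) < 2) {
      warning("stratum '", g, "' lacks one outcome class; excluded")
      next
    }
    r <- auc_empirical(score[idx], outcome[idx], orientation)
    res[[g]] <- r
    w[g] <- sum(outcome[idx] == 1, na.rm = TRUE) *
      sum(outcome[idx] == 0, na.rm = TRUE)
  }
  if (!length(res)) stop("no stratum with both outcome classes")
  w <- w / sum(w)
  auc <- sum(w * vapply(res, `[[`, numeric(1), "auc"))
  v <- sum(w^2 * vapply(res, `[[`, numeric(1), "var"))
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * sqrt(v), 0), 1)
  structure(list(auc = auc, ci = ci, var = v, method = "gender_adjusted",
                 strata = res, weights = w),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f [95%% CI %.3f, %.3f] (%s)\n",
              x$auc, x$ci[1], x$ci[2], x$method))
  invisible(x)
}

#' Paired DeLong comparison of two markers
#'
#' Tests the difference in AUC between two markers measured on the same
#' subjects (e.g. the health score versus the chronic-condition count,
#' the latter negated for orientation) with the paired DeLong test,
#' optionally stratified by gender (stratum-weighted difference and
#' variance, weights proportional to case-control pair counts).
#'
#' @param score_a,score_b the two markers; both oriented so that LOWER
#'   values predict the event (negate a count-like marker beforehand or
#'   via \code{orientation_b}).
#' @param outcome binary vector (1 = event).
#' @param gender optional stratification vector.
#' @param orientation_a,orientation_b marker orientations as in
#'   \code{\link{auc_empirical}}.
#' @return List with \code{auc_a}, \code{auc_b}, \code{delta}, \code{z}
#'   and \code{p} (two-sided).
#' @export
compare_auc <- function(score_a, score_b, outcome, gender = NULL,
                        orientation_a = "lower_predicts_event",
                        orientation_b = "lower_predicts_event") {
  ma <- if (orientation_a == "lower_predicts_event") -score_a else score_a
  mb <- if (orientation_b == "lower_predicts_event") -score_b else score_b
  if (is.null(gender)) gender <- rep(1L, length(outcome))

  strata <- split(seq_along(outcome), gender)
  deltas <- vars <- w <- numeric()
  auc_a <- auc_b <- numeric()
  for (g in names(strata)) {
    idx <- strata[[g]]
    if (length(unique(na.omit(outcome[idx]))) < 2) next
    pa <- delong_placements(ma[idx], outcome[idx])
    pb <- delong_placements(mb[idx], outcome[idx])
    s10 <- cov(cbind(pa$v10, pb$v10))
    s01 <- cov(cbind(pa$v01, pb$v01))
    vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
    deltas[g] <- pa$auc - pb$auc
    vars[g] <- vd
    auc_a[g] <- pa$auc; auc_b[g] <- pb$auc
    w[g] <- pa$m * pa$n
  }
  if (!length(deltas)) stop("no stratum with both outcome classes")
  w <- w / sum(w)
  delta <- sum(w * deltas)
  v <- sum(w^2 * vars)
  z <- if (v > 0) delta / sqrt(v) else 0
  list(auc_a = sum(w * auc_a), auc_b = sum(w * auc_b), delta = delta,
       z = z, p = if (v > 0) 2 * pnorm(-abs(z)) else 1)
}

#' Chronic-condition count
#'
#' Row-wise sum of the eight binary chronic-condition flags; missing
#' flags are treated as 0 (absent) and their number is reported in a
#' message.
#'
#' @param condition_flags data frame or matrix of 0/1 flags.
#' @return Integer vector of counts.
#' @export
chronic_count <- function(condition_flags) {
  m <- as.matrix(condition_flags)
  n_miss <- sum(is.na(m))
  if (n_miss > 0) {
    message(n_miss, " missing condition flag(s) treated as 0")
    m[is.na(m)] <- 0
  }
  as.integer(rowSums(m))
}
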