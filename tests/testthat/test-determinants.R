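# simulate from the crossed random-intercept model
lmm_data <- function(n_person = 300, n_wave = 6, sd_person = 8.43,
                     sd_wave = 1.0, sd_resid = 5.28, beta = c(50, 2, -3),
                     seed = 1) {
  set.seed(seed)
  d <- expand.grid(person = seq_len(n_person), wave = seq_len(n_wave))
  x1 <- rnorm(n_person)[d$person]
  x2 <- rbinom(n_person, 1, 0.5)[d$person]
  alpha <- rnorm(n_person, 0, sd_person)[d$person]
  gam <- rnorm(n_wave, 0, sd_wave)[d$wave]
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 + alpha + gam +
    rnorm(nrow(d), 0, sd_resid)
  data.frame(y = y, x1 = x1, x2 = x2, person = d$person, wave = d$wave)
}

test_that("mixed model recovers generating variance components", {
  d <- lmm_data(n_person = 2000, seed = 2)
  fit <- fit_lmm(d$y, d[c("x1", "x2")], d$person, d$wave)
  expect_lt(abs(fit$sd_person - 8.43) / 8.43, 0.10)
  expect_lt(abs(fit$sd_resid - 5.28) / 5.28, 0.10)
  # the wave SD has only 6 levels; just require the right order of magnitude
  expect_gt(fit$sd_wave, 0.2)
  expect_lt(fit$sd_wave, 3)
  expect_lt(max(abs(fit$coefficients$estimate[2:3] - c(2, -3))), 0.5)
  # AIC bookkeeping: -2 ll + 2 (n_fixed + 3)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * (3 + 3))
})

test_that("mixed model degenerates to OLS without clustering", {
  d <- lmm_data(n_person = 200, n_wave = 4, sd_person = 0, sd_wave = 0,
                sd_resid = 3, seed = 3)
  fit <- suppressMessages(fit_lmm(d$y, d[c("x1", "x2")], d$person, d$wave))
  ols <- lm(y ~ x1 + x2, data = d)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-4)
  # scale equivariance: doubling y doubles coefficients and SDs
  fit2 <- suppressMessages(fit_lmm(2 * d$y, d[c("x1", "x2")], d$person,
                                   d$wave))
  expect_equal(fit2$coefficients$estimate,
               2 * fit$coefficients$estimate, tolerance = 1e-4)
  expect_equal(fit2$sd_resid, 2 * fit$sd_resid, tolerance = 1e-3)
  # rank-deficient design errors with the aliased column named
  expect_error(fit_lmm(d$y, data.frame(x1 = d$x1, x1b = d$x1),
                       d$person, d$wave), "aliased")
})

test_that("LRT against the linear model detects clustering", {
  d <- lmm_data(n_person = 400, seed = 4)
  fit <- fit_lmm(d$y, d[c("x1", "x2")], d$person, d$wave)
  ols <- lm(y ~ x1 + x2, data = d)
  lrt <- lrt_vs_linear(fit, ols)
  expect_equal(lrt$df, 2L)
  expect_gt(lrt$chisq, 0)
  expect_lt(lrt$p, 1e-10)
  # identical likelihoods -> chi2 0, p 1
  same <- list(loglik = -100, k = 4)
  lrt0 <- lrt_vs_linear(same, same)
  expect_equal(lrt0$chisq, 0)
  expect_equal(lrt0$p, 1)
})

test_that("adjusted McFadden pseudo R2 matches hand arithmetic", {
  # toy likelihood pair
  full <- list(loglik = -70, k = 5)
  null <- list(loglik = -100, k = 1)
  expect_equal(mcfadden_adjusted(full, null), 1 - (-70 - 5) / -100)
  # full = null: approximately -k/ll_null (negative, near 0 for large n)
  expect_equal(mcfadden_adjusted(list(loglik = -1000, k = 3),
                                 list(loglik = -1000, k = 1)),
               1 - (-1003) / -1000)
})

test_that("conditional ICC reproduces its defining ratio", {
  # published-style random part: SDs 8.43 / 1.00 / 5.28 -> 0.72
  f <- list(sd_person = 8.43, sd_wave = 1.00, sd_resid = 5.28)
  expect_equal(round(conditional_icc(f), 2), 0.72)
  expect_equal(conditional_icc(list(sd_person = 0, sd_wave = 0,
                                    sd_resid = 2)), 0)
  expect_equal(conditional_icc(list(sd_person = 3, sd_wave = 1,
                                    sd_resid = 0)), 1)
})

test_that("standardized OLS magnitudes behave", {
  set.seed(5)
  x <- rnorm(100)
  y <- 2 * x
  t1 <- suppressWarnings(ols_standardized(y, data.frame(x = x)))$table
  expect_equal(t1$beta_std[t1$term == "x"], 1, tolerance = 1e-10)
  # orthogonal standardized predictors: beta_std ~ |cor(x, y)|
  n <- 5000
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y2 <- 0.5 * X$a - 0.3 * X$b + rnorm(n)
  t2 <- ols_standardized(y2, X)$table
  expect_equal(t2$beta_std[t2$term == "a"], abs(cor(X$a, y2)),
               tolerance = 0.05)
  expect_equal(t2$beta_std[t2$term == "b"], abs(cor(X$b, y2)),
               tolerance = 0.05)
})

test_that("empirical AUC matches brute-force pair enumeration", {
  # 2 cases at scores {1,2}, 2 controls at {3,4}; lower score = event
  score <- c(1, 2, 3, 4)
  outcome <- c(1, 1, 0, 0)
  res <- auc_empirical(score, outcome)
  # all 4 pairs concordant
  expect_equal(res$auc, 1)
  # random score: AUC near 0.5
  set.seed(6)
  s <- rnorm(4000)
  o <- rbinom(4000, 1, 0.3)
  expect_lt(abs(auc_empirical(s, o)$auc - 0.5), 0.03)
  # ties counted one half
  res2 <- auc_empirical(c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(res2$auc, 0.5)
  expect_error(auc_empirical(1:4, c(1, 1, 1, 1)), "both classes")
  # monotone-transform invariance
  s2 <- rnorm(500)
  o2 <- rbinom(500, 1, pnorm(-s2))
  expect_equal(auc_empirical(s2, o2)$auc,
               auc_empirical(exp(s2), o2)$auc)
})

test_that("AUC machinery agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- rnorm(300)
  o <- rbinom(300, 1, pnorm(-0.8 * s))
  res <- auc_empirical(s, o)
  oracle <- pROC::roc(o, s, direction = ">", quiet = TRUE)
  expect_equal(res$auc, as.numeric(pROC::auc(oracle)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(oracle, method = "delong"))
  expect_equal(res$ci[1], ci[1], tolerance = 1e-6)
  expect_equal(res$ci[2], ci[3], tolerance = 1e-6)
})

test_that("gender-adjusted AUC is a pair-weighted stratum average", {
  # identical strata: equals the pooled AUC
  set.seed(8)
  s <- rnorm(200)
  o <- rbinom(200, 1, pnorm(-s))
  g <- rep(0:1, 100)
  sa <- auc_gender_adjusted(c(s, s), c(o, o), rep(0:1, each = 200))
  pooled <- auc_empirical(s, o)
  expect_equal(sa$auc, pooled$auc, tolerance = 1e-12)
  # 12-row toy against brute-force within-stratum enumeration
  s12 <- c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 6)
  o12 <- c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 0)
  g12 <- rep(c("m", "f"), each = 6)
  brute <- function(sc, oc) {
    cases <- -sc[oc == 1]; ctrl <- -sc[oc == 0]
    mean(outer(cases, ctrl, ">") + 0.5 * outer(cases, ctrl, "=="))
  }
  a_m <- brute(s12[1:6], o12[1:6])
  a_f <- brute(s12[7:12], o12[7:12])
  w_m <- 3 * 3; w_f <- 2 * 4
  want <- (w_m * a_m + w_f * a_f) / (w_m + w_f)
  got <- auc_gender_adjusted(s12, o12, g12)
  expect_equal(got$auc, want)
  # stratum without cases is dropped with a warning
  o_bad <- o12; o_bad[7:12] <- 0
  expect_warning(res <- auc_gender_adjusted(s12, o_bad, g12), "lacks")
  expect_equal(res$auc, a_m)
})

test_that("paired DeLong comparison is calibrated and antisymmetric", {
  set.seed(9)
  n <- 400
  theta <- rnorm(n)
  o <- rbinom(n, 1, pnorm(-1 + 0.9 * theta))
  good <- -theta + rnorm(n, 0, 0.3)   # strong marker (lower = event)
  weak <- -theta + rnorm(n, 0, 3)     # weak marker
  cmp <- compare_auc(good, weak, o)
  expect_gt(cmp$delta, 0)
  expect_lt(cmp$p, 0.05)
  # antisymmetry
  cmp2 <- compare_auc(weak, good, o)
  expect_equal(cmp2$delta, -cmp$delta, tolerance = 1e-12)
  # identical markers: delta 0, p 1
  cmp3 <- compare_auc(good, good, o)
  expect_equal(cmp3$delta, 0)
  expect_equal(cmp3$p, 1)
})

test_that("paired DeLong agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(10)
  n <- 300
  theta <- rnorm(n)
  o <- rbinom(n, 1, pnorm(-0.5 + 0.8 * theta))
  m1 <- -theta + rnorm(n, 0, 0.5)
  m2 <- -theta + rnorm(n, 0, 2)
  cmp <- compare_auc(m1, m2, o)
  r1 <- pROC::roc(o, m1, direction = ">", quiet = TRUE)
  r2 <- pROC::roc(o, m2, direction = ">", quiet = TRUE)
  oracle <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(cmp$p, oracle$p.value, tolerance = 1e-6)
})

test_that("chronic counts sum flags with missing-as-zero", {
  flags <- rbind(rep(0, 8), rep(1, 8), c(1, 0, 1, 0, 0, 0, 1, 0))
  expect_equal(chronic_count(flags), c(0L, 8L, 3L))
  flags_na <- flags
  flags_na[1, 1] <- NA
  expect_message(cc <- chronic_count(flags_na), "1 missing")
  expect_equal(cc, c(0L, 8L, 3L))
})
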