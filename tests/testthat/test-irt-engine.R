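test_that("sampler EAPs match the Gauss-Hermite oracle on a 2-item test", {
  skip_if_not_installed("statmod")
  a <- c(1.2, 0.8)
  b <- c(-0.3, 0.5)
  # n = 500 persons, all four response patterns present
  set.seed(99)
  theta <- rnorm(500)
  x1 <- rbinom(500, 1, pnorm(a[1] * theta - b[1]))
  x2 <- rbinom(500, 1, pnorm(a[2] * theta - b[2]))
  panel <- make_panel(cbind(x1, x2))
  fit <- fit_mlirt(panel, toy_catalog(2),
                   mlirt_spec("M1_none", n_iter = 4000, burn_in = 200,
                              seed = 7,
                              fix_items = list(a = a, b = list(b[1], b[2])),
                              fix_sigma_u = 0, fix_sigma_theta = 1))
  eap <- eap_scores(fit)
  pat <- cbind(x1, x2)
  got <- sapply(0:3, function(code) {
    sel <- pat[, 1] == code %/% 2 & pat[, 2] == code %% 2
    mean(eap$theta_eap[sel])
  })
  want <- gh_eap_oracle(cbind(0:3 %/% 2, 0:3 %% 2), a, b)
  expect_lt(max(abs(got - want)), 0.02)

  # single binary item at b = 0, theta fixed near 0: posterior symmetric
  expect_equal(sort(unique(eap$wave)), 1L)
})

test_that("posterior-mean threshold is near truth for a symmetric item", {
  set.seed(5)
  theta <- rep(0, 400)
  x <- rbinom(400, 1, pnorm(theta - 0))
  panel <- make_panel(matrix(x, ncol = 1))
  fit <- fit_mlirt(panel, toy_catalog(1),
                   mlirt_spec("M1_none", n_iter = 1500, burn_in = 300,
                              seed = 3, fix_sigma_u = 0,
                              fix_sigma_theta = 1, rescale = FALSE,
                              prior = list(a_var = 0.0001)))
  b_hat <- mean(fit$draws$b)
  expect_lt(abs(b_hat), 3 * sd(fit$draws$b) + 0.1)
})

test_that("identification and ordering invariants hold in every draw", {
  coh <- irt_cohort(n_persons = 120, n_items = 8, seed = 19)
  panel <- filter_personwave_irt(coh$panel)
  fit <- fit_mlirt(panel, coh$catalog,
                   mlirt_spec("M4_hierarchical_full", n_iter = 400,
                              burn_in = 100, seed = 2))
  # mean slope = 1 in every retained draw
  expect_lt(max(abs(rowMeans(fit$draws$a) - 1)), 1e-10)
  # thresholds ordered in every retained draw
  off <- fit$thr_offsets
  K <- fit$catalog$items$n_cat
  for (i in seq_along(K)) {
    if (K[i] < 3) next
    blk <- fit$draws$b[, (off[i] + 1):off[i + 1], drop = FALSE]
    expect_true(all(apply(blk, 1, function(r) all(diff(r) > 0))))
  }
  # variances positive
  expect_true(all(fit$draws$sigma_u2 > 0))
  expect_true(all(fit$draws$sigma_theta2 > 0))
  # wave ICC interval contains the median
  wi <- wave_icc(fit)
  expect_gte(wi$icc, wi$ci[1])
  expect_lte(wi$icc, wi$ci[2])
})

test_that("chains are reproducible under a fixed seed", {
  coh <- irt_cohort(n_persons = 60, n_items = 6, seed = 23)
  panel <- filter_personwave_irt(coh$panel)
  spec <- mlirt_spec("M2_itemwise_intercept", n_iter = 200, burn_in = 50,
                     seed = 11)
  f1 <- suppressWarnings(fit_mlirt(panel, coh$catalog, spec))
  f2 <- suppressWarnings(fit_mlirt(panel, coh$catalog, spec))
  expect_identical(f1$draws$a, f2$draws$a)
  expect_identical(f1$theta_mean, f2$theta_mean)
  f3 <- suppressWarnings(
    fit_mlirt(panel, coh$catalog,
              mlirt_spec("M2_itemwise_intercept", n_iter = 200,
                         burn_in = 50, seed = 12)))
  expect_false(identical(f1$draws$a, f3$draws$a))
})

test_that("EAP reliability limits behave", {
  # constant chain -> psd 0 -> reliability 1
  post <- list(theta_mean = rnorm(50), theta_sd = rep(0, 50))
  expect_equal(eap_reliability(post), 1)
  # pure noise items: slopes ~ 0 -> reliability near 0
  set.seed(41)
  x <- matrix(rbinom(800 * 4, 1, 0.5), 800, 4)
  panel <- make_panel(x)
  fit <- suppressWarnings(
    fit_mlirt(panel, toy_catalog(4),
              mlirt_spec("M1_none", n_iter = 1000, burn_in = 200,
                         seed = 5, fix_sigma_u = 0,
                         fix_sigma_theta = 1, rescale = FALSE)))
  expect_lt(eap_reliability(fit), 0.3)
})

test_that("reliability grows with test length on the default generator", {
  rels <- sapply(c(5, 20), function(ni) {
    coh <- irt_cohort(n_persons = 150, n_items = ni, seed = 37,
                      drift_b = 0, drift_a = 0)
    panel <- filter_personwave_irt(coh$panel)
    fit <- fit_mlirt(panel, coh$catalog,
                     mlirt_spec("M1_none", n_iter = 400, burn_in = 100,
                                seed = 3))
    eap_reliability(fit)
  })
  expect_gt(rels[2], rels[1])
})

test_that("DIC machinery matches a direct grid oracle on a one-item toy", {
  # single binary item, fixed theta grid: compare DIC ordering of a
  # saturated (correct-b) vs misfit (wrong-b) configuration against the
  # directly computed deviance ordering
  set.seed(61)
  n <- 300
  theta <- rnorm(n)
  x <- rbinom(n, 1, pnorm(theta - 0.4))
  dev_at <- function(b) {
    p <- pnorm(theta - b)
    -2 * sum(log(ifelse(x == 1, p, 1 - p)))
  }
  # oracle: deviance minimised near the generating threshold
  grid <- seq(-1.5, 1.5, 0.05)
  expect_lt(abs(grid[which.min(sapply(grid, dev_at))] - 0.4), 0.2)

  # degenerate one-draw chain: pD = 0
  panel <- make_panel(matrix(x, ncol = 1))
  fit <- fit_mlirt(panel, toy_catalog(1),
                   mlirt_spec("M1_none", n_iter = 302, burn_in = 300,
                              thin = 2, dev_every = 1, seed = 5,
                              fix_items = list(a = 1, b = list(0.4)),
                              fix_sigma_u = 0, fix_sigma_theta = 1,
                              keep_theta_draws = TRUE))
  expect_equal(length(fit$draws$sigma_u2), 1L)
  d <- dic(fit)
  expect_equal(d$pD, 0, tolerance = 1e-9)
  expect_equal(d$DIC, d$Dbar, tolerance = 1e-9)
})

test_that("health-score transform reverses, bounds and round-trips", {
  eap <- data.frame(person_id = 1:5, wave = 1L,
                    theta_eap = c(-2, -1, 0, 1, 2), theta_psd = 0.1)
  hs <- to_health_score(eap)
  expect_equal(hs$score, c(100, 75, 50, 25, 0))
  # ranking exactly reversed
  expect_equal(order(hs$score), rev(order(eap$theta_eap)))
  # out-of-range abilities clamp with a warning
  tr <- attr(hs, "transform")
  eap2 <- data.frame(person_id = 1, wave = 1L, theta_eap = 3,
                     theta_psd = 0.1)
  expect_warning(hs2 <- to_health_score(eap2, transform = tr), "clamped")
  expect_equal(hs2$score, 0)
  # degenerate range errors
  eap3 <- data.frame(person_id = 1:2, wave = 1L, theta_eap = c(1, 1),
                     theta_psd = 0)
  expect_error(to_health_score(eap3), "degenerate")
})

test_that("sum-score correlation identifies affine and null relations", {
  coh <- small_cohort()
  panel <- coh$panel
  obs <- panel[!is.na(panel$response), ]
  ss <- aggregate(response ~ person_id + wave, data = obs, FUN = mean)
  # score an exact affine function of the mean sum -> |r| = 1
  scores <- data.frame(person_id = ss$person_id, wave = ss$wave,
                       score = 100 - 10 * ss$response)
  expect_equal(sumscore_correlation(scores, panel), 1)
  # independent noise -> |r| near 0
  set.seed(17)
  scores$score <- runif(nrow(scores), 0, 100)
  expect_lt(sumscore_correlation(scores, panel), 0.25)
})

test_that("model comparison ranks and flags as specified", {
  fake_fit <- function(rel, dic_val) {
    structure(list(theta_mean = NULL, rel = rel, dic = dic_val), class = "fake")
  }
  # single fit is selected
  coh <- irt_cohort(n_persons = 60, n_items = 6, seed = 53)
  panel <- filter_personwave_irt(coh$panel)
  f1 <- suppressWarnings(
    fit_mlirt(panel, coh$catalog,
              mlirt_spec("M1_none", n_iter = 200, burn_in = 50, seed = 1)))
  cmp1 <- compare_models(list(only = f1))
  expect_equal(cmp1$selected, "only")
  expect_true(cmp1$criteria_agree)
})
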