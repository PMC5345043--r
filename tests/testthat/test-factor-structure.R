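test_that("polychoric pairs recover known latent correlations", {
  # balanced independent 2x2 table -> rho 0
  x <- rep(c(0, 0, 1, 1), each = 25)
  y <- rep(c(0, 1, 0, 1), each = 25)
  expect_lt(abs(polychoric_pair(x, y)$rho), 1e-4)

  # latent rho = 0.5, thresholds 0: orthant P(1,1) = 1/4 + asin(0.5)/(2 pi)
  # = 1/3; build the exact expected table and check the ML estimate
  n <- 12000
  p11 <- 1 / 4 + asin(0.5) / (2 * pi)
  tab <- round(n * c(p11, 0.5 - p11, 0.5 - p11, p11))
  x <- rep(c(0, 0, 1, 1), tab)
  y <- rep(c(0, 1, 0, 1), tab)
  est <- polychoric_pair(x, y)
  expect_lt(abs(est$rho - 0.5), 0.01)
  expect_lt(abs(est$thresholds_x), 0.01)

  # perfectly concordant table clamps at the boundary
  x <- rep(0:1, each = 50)
  expect_equal(abs(polychoric_pair(x, x)$rho), 0.999)

  # degenerate margins error with the pair named
  expect_error(polychoric_pair(rep(0, 50), rep(0:1, 25)), "degenerate")

  # independent oracle: mvtnorm rectangle probabilities give the same
  # likelihood surface as the internal bivariate-normal CDF
  skip_if_not_installed("mvtnorm")
  set.seed(6)
  z <- matrix(rnorm(2000), 1000, 2)
  z[, 2] <- 0.6 * z[, 1] + sqrt(1 - 0.36) * z[, 2]
  xo <- as.integer(z[, 1] > -0.3)
  yo <- as.integer(cut(z[, 2], c(-Inf, -0.5, 0.5, Inf))) - 1L
  est <- polychoric_pair(xo, yo)
  nll_or <- function(r) {
    tab <- table(xo, yo)
    tx <- c(-Inf, est$thresholds_x, Inf)
    ty <- c(-Inf, est$thresholds_y, Inf)
    s <- matrix(c(1, r, r, 1), 2)
    ll <- 0
    for (i in 1:2) for (j in 1:3) {
      p <- mvtnorm::pmvnorm(lower = c(tx[i], ty[j]),
                            upper = c(tx[i + 1], ty[j + 1]), corr = s)[1]
      ll <- ll - tab[i, j] * log(max(p, 1e-300))
    }
    ll
  }
  rho_or <- optimize(nll_or, c(-0.999, 0.999), tol = 1e-6)$minimum
  expect_lt(abs(est$rho - rho_or), 1e-4)
})

test_that("polychoric matrices are symmetric, PSD-smoothed and honest", {
  set.seed(8)
  x <- matrix(sample(0:2, 900, replace = TRUE), 300, 3)
  colnames(x) <- c("a", "b", "c")
  pm <- polychoric_matrix(x)
  expect_true(isSymmetric(pm$rho, tol = 1e-12))
  expect_equal(diag(pm$rho), c(a = 1, b = 1, c = 1))
  # independent items: off-diagonals near zero
  expect_lt(max(abs(pm$rho[upper.tri(pm$rho)])), 0.15)
  expect_false(pm$smoothed)
  # smoothing leaves a PSD matrix untouched and repairs an indefinite one
  R_bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  sm <- healthtrait:::nearest_psd_corr(R_bad)
  expect_gte(min(eigen(sm, symmetric = TRUE)$values), -1e-10)
  expect_equal(diag(sm), rep(1, 3))
})

test_that("MAP test finds the generating number of factors", {
  # identity: minimum at 0 factors
  expect_equal(map_test(diag(8))$n_factors, 0L)

  # one-factor data, loadings 0.8
  R1 <- tcrossprod(rep(0.8, 9)) + diag(1 - 0.64, 9)
  expect_equal(map_test(R1)$n_factors, 1L)

  # 5-factor synthetic ordinal data (9 items per factor, loadings 0.7)
  x <- factor_model_data(2000, 5, 9, loading = 0.7, seed = 15)
  pm <- polychoric_matrix(x)
  mt <- map_test(pm, max_factors = 10)
  expect_equal(mt$n_factors, 5L)
  expect_length(mt$map_curve, 11)
})

test_that("minres extraction recovers a rank-one structure", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.75)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  L <- efa_minres(R, 1)
  expect_lt(max(abs(abs(L[, 1]) - lam)), 1e-4)
  # deterministic
  expect_identical(L, efa_minres(R, 1))
  # near-saturation reproduces R's off-diagonals
  x <- factor_model_data(500, 2, 4, seed = 16)
  pm <- polychoric_matrix(x)$rho
  L7 <- efa_minres(pm, ncol(pm) - 1)
  resid <- pm - tcrossprod(L7)
  diag(resid) <- 0
  expect_lt(max(abs(resid)), 0.05)
})

test_that("geomin rotation cleans up a rotated perfect-cluster pattern", {
  # perfect cluster loadings, then deliberately mixed by a rotation
  L_true <- rbind(matrix(c(0.8, 0), 4, 2, byrow = TRUE),
                  matrix(c(0, 0.7), 4, 2, byrow = TRUE))
  ang <- 0.5
  Rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2)
  sol <- rotate_geomin(L_true %*% Rot, seed = 2)
  # criterion at the solution is no worse than at the clean pattern
  crit_clean <- healthtrait:::geomin_crit(L_true, 0.01)$f
  expect_lte(sol$criterion, crit_clean + 1e-6)
  # brute-force oracle: no single oblique 2x2 rotation improves it
  grid <- expand.grid(a = seq(-0.6, 0.6, 0.05), b = seq(-0.6, 0.6, 0.05))
  crits <- apply(grid, 1, function(g) {
    Tm <- matrix(c(1, g[1], g[2], 1), 2)
    Tm <- sweep(Tm, 2, sqrt(colSums(Tm^2)), "/")
    healthtrait:::geomin_crit(sol$loadings %*% t(solve(Tm)), 0.01)$f
  })
  expect_lte(sol$criterion, min(crits) + 1e-4)
  # factor correlation matrix is a proper correlation matrix
  expect_equal(diag(sol$phi), rep(1, 2))
  expect_gte(min(eigen(sol$phi)$values), -1e-10)
  # single factor: rotation is the identity
  L1 <- matrix(c(0.8, 0.6, 0.4), 3, 1)
  expect_equal(rotate_geomin(L1)$loadings, L1)
})

test_that("item assignment applies the 0.25 cutoff inclusively", {
  L <- rbind(climb = c(0.87, 0.03, 0.13, -0.02, -0.07),
             phone = c(0.04, 0.15, 0.25, 0.33, 0.30),
             nothing = c(0.1, 0.05, 0, 0.2, 0.24))
  res <- assign_items(L, cutoff = 0.25)
  expect_equal(unname(res$assignment$climb), 1L)
  expect_equal(unname(res$assignment$phone), c(3L, 4L, 5L))
  expect_equal(res$unassigned, "nothing")
  # all-zero row unassigned
  res0 <- assign_items(matrix(0, 1, 3))
  expect_length(res0$assignment, 0)
})

test_that("explained variance proportions behave", {
  expect_equal(explained_variance(diag(4)), rep(0.25, 4))
  lam <- rep(0.8, 10)
  R <- tcrossprod(lam) + diag(1 - 0.64, 10)
  # from loadings: sum of squared loadings over p
  expect_equal(explained_variance(matrix(lam, 10, 1)), 0.64)
  # from the correlation matrix: leading eigenvalue over p
  ev <- explained_variance(R, 1)
  expect_equal(ev, (0.64 * 10 + 0.36) / 10)
  expect_lte(sum(explained_variance(R)), 1 + 1e-12)
})

test_that("fit indices follow their closed forms", {
  # perfect fit
  fi <- fit_indices(930, 930, 5000, 990, 3572)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  # worked arithmetic: chi2 = 2 * df
  fi2 <- fit_indices(930 * 2, 930, 50000, 990, 3572)
  expect_equal(fi2$rmsea, sqrt(930 / (930 * 3571)), tolerance = 1e-12)
  expect_equal(round(fi2$rmsea, 3), 0.017)
  # CI brackets the point estimate on random admissible inputs
  set.seed(21)
  for (i in 1:20) {
    df <- sample(5:50, 1)
    chi2 <- df * runif(1, 0.5, 3)
    fi3 <- fit_indices(chi2, df, chi2 * 5, df + 5, 500)
    expect_lte(fi3$rmsea_ci[["lower"]], fi3$rmsea + 1e-10)
    expect_gte(fi3$rmsea_ci[["upper"]], fi3$rmsea - 1e-10)
    expect_true(fi3$cfi >= 0 && fi3$cfi <= 1)
    expect_true(fi3$tli >= 0 && fi3$tli <= 1)
  }
})

test_that("second-order CFA recovers a generating model", {
  # population correlation matrix of a second-order model: the estimator
  # should recover the generating parameters near-exactly
  gamma <- c(0.85, 0.6, 0.45)
  lam <- c(0.8, 0.7, 0.6, 0.75, 0.65, 0.7, 0.6, 0.8, 0.55)
  idx <- rep(1:3, each = 3)
  Lmat <- matrix(0, 9, 3)
  Lmat[cbind(1:9, idx)] <- lam
  phi1 <- tcrossprod(gamma) + diag(1 - gamma^2)
  R <- Lmat %*% phi1 %*% t(Lmat)
  diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:9), paste0("v", 1:9))
  n <- 5000
  structure_list <- setNames(as.list(idx), colnames(R))
  fit <- cfa_second_order(R, structure_list, N = n)
  got_lam <- fit$loadings[cbind(1:9, idx)]
  expect_lt(max(abs(got_lam - lam)), 0.01)
  expect_lt(max(abs(fit$gamma - gamma)), 0.01)
  expect_gt(fit$fit$cfi, 0.99)
  expect_lt(fit$fit$rmsea, 0.01)

  # factor with a single indicator errors
  bad <- structure_list
  bad$v9 <- 4L
  bad$v1 <- c(1L, 4L)
  expect_error(cfa_second_order(R, setNames(as.list(c(1, 1, 2, 2, 3, 3, 4)),
                                            paste0("v", 1:7)), N = n),
               "fewer than 2 indicators")
})
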