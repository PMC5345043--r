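#' Second-order confirmatory factor model by unweighted least squares
#'
#' Fits the model R = Lambda1 Phi1 Lambda1' + diag(psi) where items load
#' on their assigned first-order factors (cross-loading items load on
#' two) and the first-order factors are connected only through a single
#' general factor: Phi1 = gamma gamma' + diag(1 - gamma^2), with
#' standardized factors. Estimation minimises the unweighted
#' least-squares discrepancy ||R - Sigma(par)||_F^2; the chi-square
#' statistic is (N - 1) times the maximum-likelihood discrepancy
#' evaluated at the ULS solution, and fit indices are computed against
#' the independence baseline.
#'
#' @param R_validation correlation matrix of the validation sample (or a
#'   \code{"polychoric_matrix"}).
#' @param structure item-to-factor assignment from
#'   \code{\link{assign_items}} (its \code{assignment} element, or the
#'   full list).
#' @param N validation sample size.
#' @return List with \code{loadings} (standardized first-order pattern),
#'   \code{gamma} (second-order loadings), \code{uniqueness},
#'   \code{fit} (a \code{\link{fit_indices}} result), \code{chisq},
#'   \code{df} and \code{converged}.
#' @export
cfa_second_order <- function(R_validation, structure, N) {
  if (inherits(R_validation, "polychoric_matrix")) {
    R_validation <- R_validation$rho
  }
  R <- as.matrix(R_validation)
  if (is.list(structure) && !is.null(structure$assignment)) {
    structure <- structure$assignment
  }
  items <- names(structure)
  miss <- setdiff(items, colnames(R))
  if (length(miss)) stop("structure names items absent from R: ",
                         paste(miss, collapse = ", "))
  R <- R[items, items]
  p <- length(items)
  m <- max(unlist(structure))
  counts <- tabulate(unlist(structure), nbins = m)
  if (any(counts < 2)) {
    stop("non-identified structure: factor(s) ",
         paste(which(counts < 2), collapse = ", "),
         " have fewer than 2 indicators")
  }

  # free loading positions
  pos <- do.call(rbind, lapply(seq_along(structure), function(i) {
    cbind(i, structure[[i]])
  }))
  n_load <- nrow(pos)
  n_par <- n_load + m + p            # loadings + gamma + uniquenesses

  build_sigma <- function(par) {
    L <- matrix(0, p, m)
    L[pos] <- par[seq_len(n_load)]
    g <- tanh(par[n_load + seq_len(m)])       # keep |gamma| < 1
    psi <- exp(par[n_load + m + seq_len(p)])
    phi1 <- tcrossprod(g) + diag(1 - g^2, m)
    list(L = L, g = g, psi = psi, S = L %*% phi1 %*% t(L) + diag(psi))
  }
  uls <- function(par) {
    S <- build_sigma(par)$S
    sum((R - S)^2)
  }

  start <- c(rep(0.6, n_load), rep(atanh(0.6), m), rep(log(0.4), p))
  fit <- optim(start, uls, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-12))
  converged <- fit$convergence == 0
  if (!converged) {
    fit2 <- optim(fit$par, uls, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-12))
    if (fit2$value <= fit$value) fit <- fit2
    converged <- fit$convergence == 0 || fit2$convergence == 0
  }
  if (!converged && fit$value > 1) {
    stop("second-order CFA failed to converge (ULS discrepancy ",
         sprintf("%.4f", fit$value), ")")
  }
  sol <- build_sigma(fit$par)

  # ML-form discrepancy at the ULS solution for the chi-square
  Sinv <- solve(sol$S)
  f_ml <- log(det(sol$S)) - log(det(R)) + sum(diag(R %*% Sinv)) - p
  f_ml <- max(f_ml, 0)
  df_m <- p * (p + 1) / 2 - n_par
  chisq_m <- (N - 1) * f_ml

  # independence baseline: Sigma = I
  f_b <- max(-log(det(R)), 0)
  chisq_b <- (N - 1) * f_b
  df_b <- p * (p - 1) / 2

  L_std <- sol$L
  dimnames(L_std) <- list(items, paste0("F", seq_len(m)))
  list(loadings = L_std, gamma = sol$g, uniqueness = sol$psi,
       fit = fit_indices(chisq_m, df_m, chisq_b, df_b, N),
       chisq = chisq_m, df = df_m, converged = converged,
       uls_value = fit$value)
}

#' Incremental and absolute fit indices from chi-square statistics
#'
#' CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m,
#' 0); TLI = ((chi2_b/df_b) - (chi2_m/df_m)) / ((chi2_b/df_b) - 1);
#' RMSEA = sqrt(max(chi2_m - df_m, 0) / (df_m (N - 1))) with a 90%
#' confidence interval from inverting the noncentral chi-square
#' distribution. CFI and TLI are clamped to [0, 1]; a baseline that fits
#' perfectly (no misfit to explain) returns CFI = TLI = 1.
#'
#' @param chi2_m,df_m model chi-square and degrees of freedom.
#' @param chi2_b,df_b baseline (independence) chi-square and df.
#' @param N sample size.
#' @return Object of class \code{"fit_indices"}: list with \code{chisq},
#'   \code{df}, \code{cfi}, \code{tli}, \code{rmsea},
#'   \code{rmsea_ci} (90% interval).
#' @export
fit_indices <- function(chi2_m, df_m, chi2_b, df_b, N) {
  stopifnot(df_m > 0, df_b > 0, N > 1)
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- chi2_b / df_b
  rm_ <- chi2_m / df_m
  tli <- if (abs(rb - 1) < 1e-12) 1 else (rb - rm_) / (rb - 1)
  cfi <- min(max(cfi, 0), 1)
  tli <- min(max(tli, 0), 1)
  rmsea <- sqrt(num / (df_m * (N - 1)))
  ci <- rmsea_ci(chi2_m, df_m, N)
  structure(list(chisq = chi2_m, df = df_m, cfi = cfi, tli = tli,
                 rmsea = rmsea, rmsea_ci = ci),
            class = "fit_indices")
}

# 90% RMSEA interval by inverting the noncentral chi-square CDF in the
# noncentrality parameter
rmsea_ci <- function(chi2, df, N, level = 0.90) {
  alpha <- (1 - level) / 2
  solve_ncp <- function(target_p) {
    if (pchisq(chi2, df) < target_p) return(0)
    hi <- max(chi2 * 2, df * 2, 10)
    while (pchisq(chi2, df, ncp = hi) > target_p && hi < 1e8) hi <- hi * 2
    uniroot(function(l) pchisq(chi2, df, ncp = l) - target_p,
            c(0, hi), tol = 1e-8)$root
  }
  lo_ncp <- solve_ncp(1 - alpha)
  hi_ncp <- solve_ncp(alpha)
  c(lower = sqrt(lo_ncp / (df * (N - 1))),
    upper = sqrt(hi_ncp / (df * (N - 1))))
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chisq(%d) = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f [%.3f, %.3f]\n",
              x$df, x$chisq, x$cfi, x$tli, x$rmsea,
              x$rmsea_ci[1], x$rmsea_ci[2]))
  invisible(x)
}
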