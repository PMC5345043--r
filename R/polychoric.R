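#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimator: thresholds from the inverse-normal cumulative
#' marginals of each variable, then the latent correlation by maximising
#' the bivariate-normal rectangle-probability likelihood of the
#' contingency table over rho. The estimate is clamped to
#' [-0.999, 0.999].
#'
#' @param x,y integer/ordinal vectors (NA allowed; pairwise deletion).
#' @return List with \code{rho}, \code{thresholds_x}, \code{thresholds_y}
#'   and \code{n} (pairwise-complete sample size).
#' @export
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate table: fewer than 2 observed categories after ",
         "pairwise deletion")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: an all-zero margin")
  }
  tx <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  ty <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  tabm <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  opt <- optimize(function(r) polychoric_negll_cpp(tabm, tx, ty, r),
                  interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- max(-0.999, min(0.999, opt$minimum))
  # the optimizer never tests the exact boundary; snap when the edge is
  # at least as good (perfectly concordant tables)
  for (edge in c(-0.999, 0.999)) {
    if (polychoric_negll_cpp(tabm, tx, ty, edge) <=
        polychoric_negll_cpp(tabm, tx, ty, rho)) {
      rho <- edge
    }
  }
  list(rho = rho, thresholds_x = unname(tx), thresholds_y = unname(ty),
       n = sum(tab))
}

#' Polychoric correlation matrix of an item response matrix
#'
#' Pairwise-complete polychoric estimates for every item pair. If the
#' resulting matrix has an eigenvalue below -1e-8 it is smoothed to the
#' nearest positive semidefinite correlation matrix (eigenvalue
#' truncation followed by rescaling to unit diagonal) and flagged.
#'
#' @param data integer matrix or data frame (rows = persons, columns =
#'   ordinal items, NA allowed).
#' @return Object of class \code{"polychoric_matrix"}: list with
#'   \code{rho} (p x p), \code{thresholds} (per item), \code{n_pairwise}
#'   (p x p) and \code{smoothed} flag.
#' @export
polychoric_matrix <- function(data) {
  m <- as.matrix(data)
  p <- ncol(m)
  if (p < 2) stop("need at least 2 items")
  R <- diag(p)
  n_pair <- matrix(0L, p, p)
  fails <- character()
  for (i in seq_len(p - 1)) {
    for (j in seq.int(i + 1, p)) {
      est <- tryCatch(polychoric_pair(m[, i], m[, j]), error = function(e) e)
      if (inherits(est, "error")) {
        fails <- c(fails, paste0(colnames(m)[i], "/", colnames(m)[j], ": ",
                                 conditionMessage(est)))
      } else {
        R[i, j] <- R[j, i] <- est$rho
        n_pair[i, j] <- n_pair[j, i] <- est$n
      }
    }
  }
  if (length(fails)) {
    stop("polychoric estimation failed for pair(s):\n  ",
         paste(fails, collapse = "\n  "))
  }
  thresholds <- lapply(seq_len(p), function(i) {
    v <- m[!is.na(m[, i]), i]
    tab <- table(v)
    unname(qnorm(cumsum(tab)[-length(tab)] / sum(tab)))
  })
  smoothed <- FALSE
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    smoothed <- TRUE
    R <- nearest_psd_corr(R)
  }
  dimnames(R) <- list(colnames(m), colnames(m))
  structure(list(rho = R, thresholds = thresholds, n_pairwise = n_pair,
                 smoothed = smoothed),
            class = "polychoric_matrix")
}

# eigenvalue-truncation smoothing to the nearest PSD correlation matrix
nearest_psd_corr <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  S <- e$vectors %*% diag(vals) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(S)))
  out <- D %*% S %*% D
  (out + t(out)) / 2
}
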