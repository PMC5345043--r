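#' Velicer's minimum average partial (MAP) test
#'
#' For m = 0, 1, ..., \code{max_factors}, partials the first m principal
#' components out of the correlation matrix and averages the squared
#' off-diagonal partial correlations; the suggested number of factors is
#' the m minimising this average (m = 0 averages the squared
#' off-diagonals of R itself, so an identity-like matrix yields 0
#' factors).
#'
#' @param R correlation matrix (or \code{"polychoric_matrix"}).
#' @param max_factors largest number of components to partial out
#'   (default p - 1).
#' @return List with \code{n_factors} and \code{map_curve} (named vector
#'   over m = 0..max_factors).
#' @export
map_test <- function(R, max_factors = NULL) {
  if (inherits(R, "polychoric_matrix")) R <- R$rho
  p <- ncol(R)
  if (is.null(max_factors)) max_factors <- p - 1L
  stopifnot(max_factors < p)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("R is not positive semidefinite")
  load_full <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))

  avg_sq <- function(M) {
    (sum(M^2) - sum(diag(M)^2)) / (p * (p - 1))
  }
  curve <- numeric(max_factors + 1)
  curve[1] <- avg_sq(R)
  for (m in seq_len(max_factors)) {
    A <- load_full[, seq_len(m), drop = FALSE]
    resid <- R - A %*% t(A)
    dres <- diag(resid)
    if (any(dres < 1e-12)) {           # component saturates an item
      curve[m + 1] <- Inf
      next
    }
    D <- diag(1 / sqrt(dres))
    curve[m + 1] <- avg_sq(D %*% resid %*% D)
  }
  names(curve) <- 0:max_factors
  list(n_factors = unname(which.min(curve)) - 1L, map_curve = curve)
}

#' Minimum-residual (OLS) exploratory factor extraction
#'
#' Extracts \code{n_factors} factors by minimising the sum of squared
#' off-diagonal residuals of R - Lambda Lambda' over the uniquenesses
#' (communalities profiled out through the eigen decomposition of the
#' reduced matrix). Columns are sign-fixed so each column's
#' largest-magnitude loading is positive. Heywood cases (communality
#' above 1) trigger a warning and are clamped.
#'
#' @param R correlation matrix (or \code{"polychoric_matrix"}).
#' @param n_factors number of factors (1 <= m < p).
#' @return Matrix of unrotated loadings (p x m).
#' @export
efa_minres <- function(R, n_factors) {
  if (inherits(R, "polychoric_matrix")) R <- R$rho
  p <- ncol(R)
  stopifnot(n_factors >= 1, n_factors < p)
  m <- n_factors

  load_from_psi <- function(psi) {
    Rr <- R - diag(psi)
    e <- eigen(Rr, symmetric = TRUE)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    L
  }
  objective <- function(psi) {
    L <- load_from_psi(psi)
    resid <- R - L %*% t(L)
    diag(resid) <- 0
    sum(resid^2) / 2
  }
  start <- 1 - 0.5 / diag(solve(R + diag(1e-8, p)))
  start <- pmin(pmax(start, 0.05), 0.95)
  fit <- optim(start, objective, method = "L-BFGS-B",
               lower = 1e-4, upper = 1, control = list(maxit = 1000))
  L <- load_from_psi(fit$par)

  h2 <- rowSums(L^2)
  if (any(h2 > 1 + 1e-6)) {
    warning(sum(h2 > 1 + 1e-6), " Heywood case(s): communalities clamped to 1")
    L[h2 > 1, ] <- L[h2 > 1, , drop = FALSE] / sqrt(h2[h2 > 1])
  }
  # sign convention per column
  for (j in seq_len(m)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("F", seq_len(m))
  L
}

# geomin criterion and gradient for a loading matrix
geomin_crit <- function(L, eps) {
  m <- ncol(L)
  L2 <- L^2 + eps
  part <- exp(rowMeans(log(L2)))
  list(f = sum(part),
       G = (2 / m) * L / L2 * part)
}

#' Geomin oblique rotation by gradient projection
#'
#' Minimises the geomin criterion sum_i (prod_j (lambda_ij^2 +
#' eps))^(1/m) over oblique rotations using the gradient projection
#' algorithm, with seeded random starts; the best criterion value wins.
#' For a single factor the rotation is the identity.
#'
#' @param loadings unrotated loading matrix (p x m).
#' @param epsilon geomin constant (default 0.01, the usual choice for
#'   3+ factors).
#' @param n_starts random rotation starts (default 10).
#' @param seed integer seed for the starts.
#' @param max_iter,tol gradient projection controls.
#' @return Object of class \code{"efa_solution"}: list with
#'   \code{loadings} (rotated pattern matrix), \code{phi} (factor
#'   correlations), \code{criterion}, and \code{explained_variance}
#'   (proportions from the unrotated solution).
#' @export
rotate_geomin <- function(loadings, epsilon = 0.01, n_starts = 10,
                          seed = 1L, max_iter = 1000, tol = 1e-6) {
  A <- as.matrix(loadings)
  m <- ncol(A)
  if (m == 1) {
    return(structure(list(loadings = A, phi = matrix(1, 1, 1),
                          criterion = geomin_crit(A, epsilon)$f,
                          explained_variance = explained_variance(A)),
                     class = "efa_solution"))
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    T0 <- if (s == 1) diag(m) else {
      M <- matrix(rnorm(m * m), m)
      Tt <- qr.Q(qr(M))
      sweep(Tt, 2, sqrt(colSums(Tt^2)), "/")
    }
    res <- gpa_oblique(A, T0, epsilon, max_iter, tol)
    if (is.null(best) || res$f < best$f) best <- res
  }
  if (!best$converged) {
    stop("geomin rotation failed to converge after ", n_starts,
         " starts; criterion trace tail: ",
         paste(sprintf("%.6f", utils::tail(best$trace, 5)), collapse = ", "))
  }
  L <- best$L
  phi <- best$phi
  # orient factors so each column's largest loading is positive
  for (j in seq_len(m)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      phi[j, ] <- -phi[j, ]
      phi[, j] <- -phi[, j]
    }
  }
  dimnames(L) <- dimnames(A)
  structure(list(loadings = L, phi = phi, criterion = best$f,
                 explained_variance = explained_variance(A)),
            class = "efa_solution")
}

# gradient projection algorithm for oblique rotation
# (criterion evaluated at L = A %*% solve(t(T)))
gpa_oblique <- function(A, Tmat, eps, max_iter, tol) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- geomin_crit(L, eps)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)   # gradient of f wrt T
  trace <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G))   # project onto constraint
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 0:10) {
      X <- Tmat - al * Gp
      X <- sweep(X, 2, sqrt(colSums(X^2)), "/")  # renormalise columns
      Xi <- try(solve(X), silent = TRUE)
      if (!inherits(Xi, "try-error")) {
        Lt <- A %*% t(Xi)
        vgt <- geomin_crit(Lt, eps)
        if (vgt$f < f - 0.5 * s^2 * al * 1e-4) {
          Tmat <- X; Ti <- Xi; L <- Lt; f <- vgt$f
          G <- -t(t(L) %*% vgt$G %*% Ti)
          break
        }
      }
      al <- al / 2
    }
    trace <- c(trace, f)
  }
  list(L = L, phi = t(Tmat) %*% Tmat, f = f, converged = converged,
       trace = trace)
}

#' Assign items to factors by a loading cutoff
#'
#' An item is assigned to every factor on which its absolute rotated
#' loading is at least \code{cutoff} (ties at the cutoff included);
#' items qualifying on no factor are reported unassigned.
#'
#' @param loadings rotated pattern matrix (p x m) or
#'   \code{"efa_solution"}.
#' @param cutoff absolute-loading threshold (default 0.25).
#' @return List with \code{assignment} (named list: item -> factor
#'   indices) and \code{unassigned} (character vector).
#' @export
assign_items <- function(loadings, cutoff = 0.25) {
  if (inherits(loadings, "efa_solution")) loadings <- loadings$loadings
  L <- as.matrix(loadings)
  items <- rownames(L)
  if (is.null(items)) items <- paste0("item", seq_len(nrow(L)))
  assignment <- lapply(seq_len(nrow(L)), function(i) {
    which(abs(L[i, ]) >= cutoff)
  })
  names(assignment) <- items
  unassigned <- items[lengths(assignment) == 0]
  list(assignment = assignment[lengths(assignment) > 0],
       unassigned = unassigned)
}

#' Proportion of total variance explained by extracted factors
#'
#' From a correlation matrix, the proportions are the leading
#' eigenvalues over p; from a loading matrix, the column sums of squared
#' loadings over p.
#'
#' @param x correlation matrix with attribute of interest, eigenvalue
#'   vector, or loading matrix (p x m).
#' @param n_factors number of leading eigenvalues to report when
#'   \code{x} is a correlation matrix.
#' @return Vector of proportions (sums to at most 1).
#' @export
explained_variance <- function(x, n_factors = NULL) {
  if (is.matrix(x) && nrow(x) == ncol(x) && isSymmetric(unname(x))) {
    ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
    p <- ncol(x)
    if (is.null(n_factors)) n_factors <- p
    ev[seq_len(n_factors)] / p
  } else if (is.matrix(x)) {
    colSums(x^2) / nrow(x)
  } else {
    x / length(x)
  }
}
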