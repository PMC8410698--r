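#' Functional principal component analysis
#'
#' Eigenanalysis of the sample covariance operator of a set of functions,
#' solved exactly in B-spline coefficient space. With centered coefficient
#' matrix `C` (N x K) and basis Gram matrix `W`, the operator eigenproblem
#' `V beta = rho beta` reduces to the symmetric K x K eigenproblem of
#' `(1/N) W^{1/2} t(C) C W^{1/2}`; eigenvectors `u` map back to
#' eigenfunction coefficient vectors `b = W^{-1/2} u`. The eigenfunctions
#' are then orthonormal in the functional (L2) inner product,
#' `t(b_j) W b_l = delta_jl`, and each satisfies the unit-norm constraint
#' `integral(beta_j^2) = 1`. Because the Gram matrix is exact for piecewise
#' polynomials, no grid discretization error enters.
#'
#' Functions are mean-centered before the covariance is formed (classical
#' PCA practice; the score-variance interpretation presupposes it);
#' `center = FALSE` instead diagonalizes the raw second-moment operator.
#'
#' At most `N - 1` eigenvalues can be nonzero for centered data: the
#' centered functions span a subspace of dimension at most `N - 1`.
#'
#' Each eigenfunction's sign is fixed by making its largest-magnitude
#' coefficient positive, so results are reproducible across eigensolvers.
#'
#' @param fd a [fit_functional()] result.
#' @param n_components number of components `m` to keep;
#'   `m <= min(K, N - 1)`. Default: all `min(K, N - 1)`.
#' @param center logical; subtract the mean function first (default TRUE).
#' @return object of class `fpca_model`: list with `basis`, `gram`,
#'   `mean_coefficients` (K), `eigenfunctions` (`m x K` coefficient rows),
#'   `eigenvalues` (non-increasing, >= 0), `n_components`, `centered`.
#' @export
fpca <- function(fd, n_components = NULL, center = TRUE) {
  stopifnot(inherits(fd, "functional_set"))
  C <- fd$coefficients
  N <- nrow(C)
  K <- ncol(C)
  if (N < 2L) stop("need at least 2 functions")
  m_max <- min(K, N - 1L)
  if (is.null(n_components)) n_components <- m_max
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("`n_components` must be >= 1")
  if (n_components > m_max)
    stop("`n_components` (", n_components, ") exceeds the rank bound ",
         "min(K, N - 1) = ", m_max,
         ": at most N - 1 eigenvalues can be nonzero")
  W <- bspline_gram(fd$basis)
  eW <- eigen(W, symmetric = TRUE)
  wv <- pmax(eW$values, 1e-12)
  W_half <- eW$vectors %*% (sqrt(wv) * t(eW$vectors))
  W_half_inv <- eW$vectors %*% ((1 / sqrt(wv)) * t(eW$vectors))
  mu <- if (center) colMeans(C) else numeric(K)
  Cc <- sweep(C, 2L, mu, "-")
  A <- Cc %*% W_half
  M <- crossprod(A) / N
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- seq_len(n_components)
  values <- pmax(eM$values[keep], 0)
  B <- W_half_inv %*% eM$vectors[, keep, drop = FALSE]   # K x m
  for (j in seq_len(ncol(B))) {
    if (B[which.max(abs(B[, j])), j] < 0) B[, j] <- -B[, j]
  }
  structure(
    list(basis = fd$basis, gram = W, mean_coefficients = mu,
         eigenfunctions = t(B), eigenvalues = values,
         n_components = n_components, centered = isTRUE(center)),
    class = "fpca_model"
  )
}

#' @export
print.fpca_model <- function(x, ...) {
  cat("fpca_model:", x$n_components, "components, K =", x$basis$n_basis, "\n")
  tot <- sum(x$eigenvalues)
  cat("  leading eigenvalues:",
      paste(format(utils::head(x$eigenvalues, 5), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Principal component scores of functions
#'
#' Projects functions onto the model's eigenfunctions:
#' `f_ij = integral(beta_j(t) * (x_i(t) - mean(t)) dt)`, computed exactly in
#' coefficient space as `(C_i - mean)' W b_j`. The functions must be
#' represented in the model's own basis.
#'
#' @param model an [fpca()] model.
#' @param fd a `functional_set` in the same basis.
#' @return `N x m` score matrix.
#' @export
fpca_scores <- function(model, fd) {
  stopifnot(inherits(model, "fpca_model"), inherits(fd, "functional_set"))
  if (model$basis$order != fd$basis$order ||
      !isTRUE(all.equal(model$basis$knots, fd$basis$knots, tolerance = 0)))
    stop("functional data basis does not match the model basis")
  Cc <- sweep(fd$coefficients, 2L, model$mean_coefficients, "-")
  Cc %*% model$gram %*% t(model$eigenfunctions)
}
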