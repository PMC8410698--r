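#' Principal component analysis of discrete spectra
#'
#' Classical PCA of the rows of an `N x p` intensity matrix: the loadings
#' are the leading eigenvectors of the sample covariance of the
#' mean-centered rows, each maximizing the mean-square score subject to unit
#' norm and orthogonality to the earlier components. The `1/N` (population)
#' covariance normalization is used throughout the package so that the
#' discrete and functional arms of a comparison share one convention.
#'
#' The computation goes through the thin singular value decomposition of
#' the centered data matrix, which is contract-equivalent to the covariance
#' eigenproblem but numerically preferable, and cheap when `N << p`. Signs
#' are fixed by making each loading's largest-magnitude entry positive.
#'
#' @param x a [spectra_set()] or numeric `N x p` matrix.
#' @param n_components number of components `m <= min(p, N - 1)`.
#' @return object of class `pca_model`: list with `mean` (p), `loadings`
#'   (`m x p`, orthonormal rows), `eigenvalues` (non-increasing),
#'   `n_components`.
#' @export
spectra_pca <- function(x, n_components = NULL) {
  X <- if (inherits(x, "spectra_set")) x$intensities else as.matrix(x)
  N <- nrow(X)
  p <- ncol(X)
  if (N < 2L) stop("need at least 2 spectra")
  m_max <- min(p, N - 1L)
  if (is.null(n_components)) n_components <- m_max
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("`n_components` must be >= 1")
  if (n_components > m_max)
    stop("`n_components` (", n_components, ") exceeds min(p, N - 1) = ", m_max)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc, nu = 0, nv = n_components)
  loadings <- t(sv$v)                       # m x p
  for (j in seq_len(nrow(loadings))) {
    if (loadings[j, which.max(abs(loadings[j, ]))] < 0)
      loadings[j, ] <- -loadings[j, ]
  }
  structure(
    list(mean = mu, loadings = loadings,
         eigenvalues = (sv$d[seq_len(n_components)]^2) / N,
         n_components = n_components),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", x$n_components, "components, p =", length(x$mean), "\n")
  cat("  leading eigenvalues:",
      paste(format(utils::head(x$eigenvalues, 5), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project spectra into a fitted principal component space
#'
#' `scores = (x - mean) %*% t(loadings)`. Projecting the training mean gives
#' the zero score vector.
#'
#' @param model a [spectra_pca()] model.
#' @param x a `spectra_set` or matrix with the model's column count.
#' @return `N x m` score matrix.
#' @export
pca_scores <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  X <- if (inherits(x, "spectra_set")) x$intensities else as.matrix(x)
  if (ncol(X) != length(model$mean))
    stop("spectra have ", ncol(X), " points but the model expects ",
         length(model$mean))
  sweep(X, 2L, model$mean, "-") %*% t(model$loadings)
}
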