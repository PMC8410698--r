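#' Least-squares functional approximation of discrete spectra
#'
#' Represents each spectrum as a function `x_i(t) = sum_k c_ik phi_k(t)` in
#' the given B-spline basis, with coefficients chosen to minimize the sum of
#' squared errors against the sampled values. The minimization is solved by
#' QR decomposition of the grid-evaluated basis matrix (one factorization is
#' shared by all spectra), which is numerically preferable to forming the
#' normal equations explicitly.
#'
#' @param spectra a [spectra_set()] whose grid lies inside the basis domain.
#' @param basis a [bspline_basis()].
#' @return object of class `functional_set`: list with `basis`,
#'   `coefficients` (`N x K`), `labels`, `batches`, `grid` (the source
#'   grid) and `fit_sse` (per-spectrum residual sum of squares).
#' @export
fit_functional <- function(spectra, basis) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(basis, "bspline_basis"))
  grid <- spectra$grid
  if (min(grid) < basis$domain[1] - 1e-12 || max(grid) > basis$domain[2] + 1e-12)
    stop("spectra grid extends outside the basis domain")
  Phi <- eval_basis(basis, grid)
  qr_Phi <- qr(Phi)
  if (qr_Phi$rank < basis$n_basis)
    stop("basis design matrix is rank deficient (K = ", basis$n_basis,
         ", p = ", length(grid), "); reduce the number of basis functions")
  Y <- t(spectra$intensities)            # p x N
  C <- qr.coef(qr_Phi, Y)                # K x N
  resid <- Y - Phi %*% C
  structure(
    list(basis = basis, coefficients = t(C), labels = spectra$labels,
         batches = spectra$batches, grid = grid,
         fit_sse = unname(colSums(resid^2))),
    class = "functional_set"
  )
}

#' @export
print.functional_set <- function(x, ...) {
  cat("functional_set:", nrow(x$coefficients), "functions, K =",
      x$basis$n_basis, "order =", x$basis$order, "\n")
  cat("  total SSE on source grid:", format(sum(x$fit_sse)), "\n")
  invisible(x)
}

#' Subset a functional_set by row
#' @param x a `functional_set`.
#' @param i function (row) indices.
#' @param ... unused.
#' @export
`[.functional_set` <- function(x, i, ...) {
  structure(
    list(basis = x$basis,
         coefficients = x$coefficients[i, , drop = FALSE],
         labels = x$labels[i],
         batches = if (!is.null(x$batches)) x$batches[i],
         grid = x$grid, fit_sse = x$fit_sse[i]),
    class = "functional_set"
  )
}

#' Evaluate fitted functions at arbitrary axis points
#'
#' @param fd a [fit_functional()] result.
#' @param points evaluation points inside the basis domain.
#' @return `N x length(points)` matrix of function values.
#' @export
eval_functional <- function(fd, points) {
  stopifnot(inherits(fd, "functional_set"))
  Phi <- eval_basis(fd$basis, points)
  fd$coefficients %*% t(Phi)
}

#' Elbow point of a size-versus-error curve
#'
#' Given model sizes and their errors, both axes are min-max normalized to
#' `[0, 1]` (sizes and errors live on incommensurate scales) and the point
#' with the largest perpendicular distance to the chord joining the first
#' and last points is returned. Ties, including the fully degenerate case of
#' an exactly linear curve, resolve to the smallest size.
#'
#' @param sizes ascending numeric vector (length >= 3).
#' @param errors numeric vector of the same length.
#' @return list with `selected` (the chosen size), `index`, and `distance`
#'   (per-candidate chord distances on the normalized axes).
#' @export
elbow_point <- function(sizes, errors) {
  sizes <- as.numeric(sizes)
  errors <- as.numeric(errors)
  if (length(sizes) < 3L) stop("need at least 3 candidates for the elbow")
  if (length(errors) != length(sizes)) stop("`sizes`/`errors` length mismatch")
  if (is.unsorted(sizes, strictly = TRUE)) stop("`sizes` must be ascending")
  norm01 <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  xs <- norm01(sizes)
  ys <- norm01(errors)
  x1 <- xs[1L]; y1 <- ys[1L]
  x2 <- xs[length(xs)]; y2 <- ys[length(ys)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- if (len == 0) rep(0, length(xs)) else
    abs((x2 - x1) * (y1 - ys) - (x1 - xs) * (y2 - y1)) / len
  # ties (within numerical noise of the maximum) resolve to the smallest size
  idx <- which(d >= max(d) - 1e-12)[1L]
  list(selected = sizes[idx], index = idx, distance = d)
}

#' Select the number of basis functions by the elbow method
#'
#' Fits every candidate basis size to the spectra, computes the
#' root-mean-square error pooled over all spectra and grid points, and
#' picks the candidate whose (size, RMSE) point lies farthest from the
#' straight line joining the first and last candidates (see
#' [elbow_point()]). One basis size is selected per dataset, shared by all
#' spectra.
#'
#' @param spectra a [spectra_set()].
#' @param candidates ascending candidate basis sizes (>= 3 of them); the
#'   default spans 10 to 300 in steps of 10, clipped to the number of grid
#'   points.
#' @param order spline order (default cubic, 4).
#' @return list with `n_basis` (selected size), `candidates`, `rmse` and
#'   `distance`.
#' @export
select_nbasis_elbow <- function(spectra,
                                candidates = seq(10L, 300L, by = 10L),
                                order = 4L) {
  stopifnot(inherits(spectra, "spectra_set"))
  p <- length(spectra$grid)
  candidates <- candidates[candidates <= p]
  if (length(candidates) < 3L)
    stop("need at least 3 feasible candidates for the elbow")
  n_total <- nrow(spectra$intensities) * p
  dom <- range(spectra$grid)
  rmse <- vapply(candidates, function(K) {
    fd <- fit_functional(spectra, bspline_basis(dom, K, order))
    sqrt(sum(fd$fit_sse) / n_total)
  }, numeric(1))
  eb <- elbow_point(candidates, rmse)
  list(n_basis = eb$selected, candidates = candidates, rmse = rmse,
       distance = eb$distance)
}
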