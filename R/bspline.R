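#' Clamped B-spline basis system
#'
#' Constructs a B-spline basis of order `order` (degree `order - 1`) with
#' `n_basis` functions on the closed interval `domain`. The knot vector is
#' clamped: the boundary knots are repeated `order` times, and the
#' `n_basis - order` interior knots are equally spaced strictly inside the
#' domain. A clamped knot vector makes the basis a partition of unity on the
#' whole domain and lets the first/last basis function interpolate the
#' endpoints, so constant spectra (and spectra values at the boundary pixels)
#' are exactly representable.
#'
#' @param domain numeric length-2, the closed interval carrying the
#'   (normalized) spectral axis. Default `c(0, 1)`.
#' @param n_basis number of basis functions `K`; must satisfy
#'   `n_basis >= order`.
#' @param order spline order `O` (polynomial degree plus one). `order = 4`
#'   gives the cubic splines conventionally used for spectral data.
#' @return An object of class `bspline_basis`: a list with elements `order`,
#'   `n_basis`, `knots` (length `n_basis + order`, non-decreasing) and
#'   `domain`.
#' @examples
#' b <- bspline_basis(c(0, 1), n_basis = 10, order = 4)
#' Phi <- eval_basis(b, seq(0, 1, length.out = 101))
#' range(rowSums(Phi))  # partition of unity
#' @export
bspline_basis <- function(domain = c(0, 1), n_basis = 190L, order = 4L) {
  if (length(domain) != 2L || !all(is.finite(domain)))
    stop("`domain` must be two finite numbers")
  if (domain[2L] <= domain[1L])
    stop("`domain` must be a non-degenerate increasing interval")
  order <- as.integer(order)
  n_basis <- as.integer(n_basis)
  if (is.na(order) || order < 1L) stop("`order` must be an integer >= 1")
  if (is.na(n_basis) || n_basis < order)
    stop("`n_basis` (", n_basis, ") must be at least `order` (", order, ")")
  n_interior <- n_basis - order
  interior <- if (n_interior > 0L) {
    seq(domain[1L], domain[2L], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else {
    numeric(0)
  }
  knots <- c(rep(domain[1L], order), interior, rep(domain[2L], order))
  structure(
    list(order = order, n_basis = n_basis, knots = knots,
         domain = as.numeric(domain)),
    class = "bspline_basis"
  )
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat("B-spline basis: K =", x$n_basis, " order =", x$order,
      " domain = [", x$domain[1], ",", x$domain[2], "]\n")
  cat("  interior knots:", x$n_basis - x$order,
      " total knots:", length(x$knots), "\n")
  invisible(x)
}

#' Evaluate a B-spline basis by the Cox-de Boor recursion
#'
#' Computes the design matrix of basis values at `x`. Order-1 functions are
#' the indicators of the half-open knot spans; higher orders follow the
#' two-term Cox-de Boor recursion. Two conventions are applied that the bare
#' recursion leaves open: any term whose knot-difference denominator is zero
#' is taken as zero (required for the repeated knots of a clamped vector),
#' and the final knot span is closed on the right so the right domain
#' endpoint is representable (the last basis function equals 1 there).
#'
#' @param basis a [bspline_basis()] object.
#' @param x numeric vector of evaluation points; every point must lie inside
#'   the closed basis domain.
#' @return numeric matrix, `length(x)` rows by `basis$n_basis` columns;
#'   entry `(j, k)` is the k-th order-`O` basis function at `x[j]`. Entries
#'   are non-negative and each function vanishes outside its knot support.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "bspline_basis"))
  x <- as.numeric(x)
  if (length(x) == 0L) return(matrix(0, 0L, basis$n_basis))
  if (anyNA(x)) stop("evaluation points must be finite")
  dom <- basis$domain
  tol <- 1e-12 * max(1, abs(dom))
  if (any(x < dom[1L] - tol) || any(x > dom[2L] + tol))
    stop("evaluation points outside the basis domain [",
         dom[1L], ", ", dom[2L], "]")
  x <- pmin(pmax(x, dom[1L]), dom[2L])
  knots <- basis$knots
  nk <- length(knots)
  O <- basis$order

  # order 1: half-open span indicators, right-closed at the domain end
  B <- matrix(0, length(x), nk - 1L)
  for (k in seq_len(nk - 1L)) {
    if (knots[k] < knots[k + 1L])
      B[, k] <- as.numeric(x >= knots[k] & x < knots[k + 1L])
  }
  last_span <- max(which(diff(knots) > 0))
  B[x >= dom[2L], last_span] <- 1

  if (O > 1L) {
    for (o in 2:O) {
      nb <- nk - o
      Bn <- matrix(0, length(x), nb)
      for (k in seq_len(nb)) {
        d1 <- knots[k + o - 1L] - knots[k]
        d2 <- knots[k + o] - knots[k + 1L]
        v <- 0
        if (d1 > 0) v <- (x - knots[k]) / d1 * B[, k]
        if (d2 > 0) v <- v + (knots[k + o] - x) / d2 * B[, k + 1L]
        Bn[, k] <- v
      }
      B <- Bn
    }
  }
  B
}

#' Gram matrix of a B-spline basis
#'
#' Returns the `K x K` matrix of pairwise L2 inner products
#' `W[k, l] = integral of phi_k(t) phi_l(t) dt` over the basis domain. The
#' integral is evaluated span by span with an `order`-node Gauss-Legendre
#' rule, which is exact for the piecewise-polynomial integrand (degree at
#' most `2 * order - 2` per span). `W` is symmetric positive semi-definite
#' and banded: entries with `|k - l| >= order` are exactly zero because the
#' supports are disjoint.
#'
#' The Gram matrix is what turns coefficient-space arithmetic into
#' functional arithmetic: for functions with coefficient vectors `c`, `d`
#' the L2 inner product is `t(c) %*% W %*% d`.
#'
#' @param basis a [bspline_basis()] object.
#' @return symmetric `K x K` numeric matrix.
#' @export
bspline_gram <- function(basis) {
  stopifnot(inherits(basis, "bspline_basis"))
  brk <- unique(basis$knots)
  nspan <- length(brk) - 1L
  nq <- max(basis$order, 2L)
  ref <- pracma::gaussLegendre(nq, 0, 1)
  nodes <- numeric(nspan * nq)
  weights <- numeric(nspan * nq)
  for (s in seq_len(nspan)) {
    h <- brk[s + 1L] - brk[s]
    idx <- (s - 1L) * nq + seq_len(nq)
    nodes[idx] <- brk[s] + h * ref$x
    weights[idx] <- h * ref$w
  }
  Phi <- eval_basis(basis, nodes)
  W <- crossprod(Phi, Phi * weights)
  (W + t(W)) / 2
}

#' Serialize / restore a basis system
#'
#' `basis_to_json()` writes the order and knot vector as JSON;
#' `basis_from_json()` rebuilds the identical `bspline_basis` object.
#'
#' @param basis a [bspline_basis()] object.
#' @param path file to write (`basis_to_json`) or read (`basis_from_json`).
#' @return `basis_to_json()` returns `path` invisibly; `basis_from_json()`
#'   returns the restored `bspline_basis`.
#' @export
basis_to_json <- function(basis, path) {
  stopifnot(inherits(basis, "bspline_basis"))
  jsonlite::write_json(
    list(order = basis$order, n_basis = basis$n_basis,
         knots = basis$knots, domain = basis$domain),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname basis_to_json
#' @export
basis_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(order = as.integer(obj$order), n_basis = as.integer(obj$n_basis),
         knots = as.numeric(obj$knots), domain = as.numeric(obj$domain)),
    class = "bspline_basis"
  )
}
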