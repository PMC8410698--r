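# Independent reference implementations used to validate the production
# code paths. These deliberately take the slow, direct route.

# Scalar Cox-de Boor recursion, written directly from the two-term
# definition (0/0 terms dropped). Valid for points strictly inside the
# domain, where the half-open/closed endpoint convention is immaterial.
naive_bspline <- function(k, o, t, knots) {
  if (o == 1L) {
    return(as.numeric(t >= knots[k] && t < knots[k + 1L]))
  }
  v <- 0
  d1 <- knots[k + o - 1L] - knots[k]
  if (d1 > 0) v <- v + (t - knots[k]) / d1 * naive_bspline(k, o - 1L, t, knots)
  d2 <- knots[k + o] - knots[k + 1L]
  if (d2 > 0) v <- v + (knots[k + o] - t) / d2 * naive_bspline(k + 1L, o - 1L, t, knots)
  v
}

# Dense-grid FPCA: evaluate the functions on a fine grid, run weighted
# discrete PCA with trapezoid quadrature weights. Basis evaluation goes
# through splines::splineDesign, independent of the package recursion.
fpca_grid_oracle <- function(coefficients, knots, order, center = TRUE,
                             n_grid = 120001L, new_coefficients = NULL) {
  dom <- range(knots)
  x <- seq(dom[1], dom[2], length.out = n_grid)
  Phi <- splines::splineDesign(knots, x, ord = order)
  Y <- coefficients %*% t(Phi)
  N <- nrow(Y)
  h <- diff(x)
  w <- c(h / 2, 0) + c(0, h / 2)          # trapezoid weights
  mu <- if (center) colMeans(Y) else numeric(ncol(Y))
  Yc <- sweep(Y, 2L, mu, "-")
  A <- sweep(Yc, 2L, sqrt(w), "*")
  e <- eigen(tcrossprod(A) / N, symmetric = TRUE)
  values <- pmax(e$values, 0)
  scores_of <- function(Cnew) {
    Ynew <- sweep(Cnew %*% t(Phi), 2L, mu, "-")
    Anew <- sweep(Ynew, 2L, sqrt(w), "*")
    sapply(seq_len(N - 1L), function(j) {
      beta_w <- crossprod(A, e$vectors[, j]) / sqrt(N * values[j])
      as.numeric(Anew %*% beta_w)
    })
  }
  train_scores <- sweep(e$vectors[, seq_len(N - 1L), drop = FALSE], 2L,
                        sqrt(N * values[seq_len(N - 1L)]), "*")
  list(values = values, train_scores = train_scores, scores_of = scores_of)
}

# Kruskal-Wallis H from first principles: average ranks, tie correction.
kw_brute <- function(a, b) {
  x <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  r <- rank(x)
  n <- length(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exhaustive Mahalanobis classifier under a pooled covariance.
mahalanobis_brute <- function(X, means, cov_pooled, class_labels) {
  inv <- solve(cov_pooled)
  apply(X, 1L, function(x) {
    d <- apply(means, 1L, function(mu) {
      v <- x - mu
      as.numeric(t(v) %*% inv %*% v)
    })
    class_labels[which.min(d)]
  })
}

# Small random spectra_set for structural tests.
make_test_spectra <- function(n = 20L, p = 60L, seed = 1L, n_classes = 2L) {
  set.seed(seed)
  labs <- rep(paste0("c", seq_len(n_classes)), length.out = n)
  spectra_set(matrix(rnorm(n * p), n, p), seq(0, 1, length.out = p), labs)
}
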