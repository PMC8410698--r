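#' Linear discriminant analysis on component scores
#'
#' Fisher discriminant analysis of an `N x m` score matrix with class
#' labels. The between-class scatter is
#' `B = sum_l n_l (mean_l - mean)(mean_l - mean)'` and the within-class
#' scatter is the pooled per-member scatter around the class means. The
#' `L - 1` discriminant directions are the leading eigenvectors of
#' `W^{-1} B`, obtained stably by Cholesky whitening of `W` followed by a
#' symmetric eigensolve. The bias is `b0 = -Omega %*% overall_mean`, so
#' discriminant coordinates `LD = Omega %*% beta + b0` are centered at the
#' data mean.
#'
#' A singular within-class scatter is an error by design: it signals more
#' components than the training data can support. `ridge` adds
#' `ridge * I` to the within scatter as an explicit escape hatch (off by
#' default).
#'
#' @param scores numeric `N x m` matrix of component scores.
#' @param labels length-`N` class labels; every class needs >= 2 members.
#' @param ridge non-negative diagonal loading of the within scatter.
#' @return object of class `slda_model`: list with `class_labels` (sorted),
#'   `counts`, `class_means` (`L x m`), `overall_mean`, `within_scatter`,
#'   `between_scatter`, `directions` (`(L-1) x m` rows of Omega), `bias`,
#'   `eigenvalues` (Fisher criterion per direction).
#' @export
lda_fit <- function(scores, labels, ridge = 0) {
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("`labels` length must match rows")
  classes <- sort(unique(labels))
  L <- length(classes)
  if (L < 2L) stop("need at least 2 classes")
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < 2L))
    stop("every class needs at least 2 members (offending: ",
         paste(classes[counts < 2L], collapse = ", "), ")")
  m <- ncol(X)
  N <- nrow(X)
  mu <- colMeans(X)
  mu_l <- matrix(0, L, m)
  for (l in seq_len(L))
    mu_l[l, ] <- colMeans(X[labels == classes[l], , drop = FALSE])
  Bs <- matrix(0, m, m)
  for (l in seq_len(L)) {
    d <- mu_l[l, ] - mu
    Bs <- Bs + counts[l] * tcrossprod(d)
  }
  Xw <- X - mu_l[match(labels, classes), , drop = FALSE]
  Ws <- crossprod(Xw)
  if (ridge > 0) Ws <- Ws + diag(ridge, m)
  R <- tryCatch(chol(Ws), error = function(e)
    stop("within-class scatter is singular; reduce `n_components` ",
         "(or set a small `ridge`)", call. = FALSE))
  # M = R^{-T} B R^{-1}, symmetric; eigenvectors map back through R^{-1}
  Z <- backsolve(R, Bs, transpose = TRUE)
  M <- t(backsolve(R, t(Z), transpose = TRUE))
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ndir <- min(L - 1L, m)
  U <- eM$vectors[, seq_len(ndir), drop = FALSE]
  Omega <- t(backsolve(R, U))               # ndir x m
  structure(
    list(class_labels = classes, counts = counts, class_means = mu_l,
         overall_mean = mu, within_scatter = Ws, between_scatter = Bs,
         directions = Omega, bias = as.numeric(-Omega %*% mu),
         eigenvalues = eM$values[seq_len(ndir)], chol_within = R),
    class = "slda_model"
  )
}

#' @export
print.slda_model <- function(x, ...) {
  cat("slda_model:", length(x$class_labels), "classes,",
      nrow(x$directions), "discriminant direction(s), m =",
      ncol(x$directions), "\n")
  invisible(x)
}

#' Classify score vectors with a fitted discriminant model
#'
#' Assigns each row to the class whose mean is nearest in Mahalanobis
#' distance under the pooled within-class covariance — the standard
#' equal-prior linear discriminant rule (classes in the study designs are
#' balanced). Ties resolve to the lexicographically smallest class label.
#'
#' @param model an [lda_fit()] model.
#' @param scores numeric matrix with the model's column count.
#' @return character vector of predicted class labels.
#' @export
lda_predict <- function(model, scores) {
  stopifnot(inherits(model, "slda_model"))
  X <- as.matrix(scores)
  m <- ncol(model$class_means)
  if (ncol(X) != m)
    stop("scores have ", ncol(X), " columns but the model expects ", m)
  R <- model$chol_within   # any positive multiple of the pooled covariance
  L <- length(model$class_labels)
  D2 <- matrix(0, nrow(X), L)
  for (l in seq_len(L)) {
    d <- sweep(X, 2L, model$class_means[l, ], "-")
    Y <- backsolve(R, t(d), transpose = TRUE)
    D2[, l] <- colSums(Y^2)
  }
  # which.min returns the first minimum; class_labels are sorted, so ties
  # fall to the lexicographically smallest label
  model$class_labels[apply(D2, 1L, which.min)]
}
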