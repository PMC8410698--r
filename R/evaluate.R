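#' Cross-validation fold assignments
#'
#' `scheme = "kfold"` builds `k` stratified folds: within every class the
#' (shuffled) members are dealt round-robin over the folds, so class
#' proportions are preserved to within one member. `scheme = "lobo"`
#' (leave one batch out) builds one fold per distinct batch label.
#'
#' @param labels class labels.
#' @param k number of folds for `"kfold"`; must not exceed the smallest
#'   class size.
#' @param scheme `"kfold"` or `"lobo"`.
#' @param batches batch labels, required for `"lobo"`.
#' @param seed integer seed controlling the shuffle.
#' @return list of folds, each a list with integer index vectors `train`
#'   and `test`; the test sets partition `seq_along(labels)`.
#' @export
make_folds <- function(labels, k = 10L, scheme = c("kfold", "lobo"),
                       batches = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  n <- length(labels)
  idx <- seq_len(n)
  if (scheme == "lobo") {
    if (is.null(batches)) stop("`lobo` cross-validation requires batch labels")
    batches <- as.character(batches)
    if (length(batches) != n) stop("`batches` length must match `labels`")
    ub <- sort(unique(batches))
    return(lapply(ub, function(b) {
      test <- idx[batches == b]
      list(train = setdiff(idx, test), test = test)
    }))
  }
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  tab <- table(labels)
  if (k > min(tab))
    stop("`k` (", k, ") exceeds the smallest class size (", min(tab), ")")
  set.seed(as.integer(seed))
  fold_id <- integer(n)
  for (cl in names(tab)) {
    members <- sample(idx[labels == cl])
    fold_id[members] <- rep_len(seq_len(k), length(members))
  }
  lapply(seq_len(k), function(f) {
    test <- idx[fold_id == f]
    list(train = idx[fold_id != f], test = test)
  })
}

#' Mean sensitivity of a confusion matrix
#'
#' The average over classes of per-class recall: `diag / rowSums`, rows
#' being the true classes. True classes with no members are excluded with a
#' warning.
#'
#' @param confusion square `L x L` count matrix, rows = true classes.
#' @return scalar in `[0, 1]`.
#' @export
mean_sensitivity <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  rs <- rowSums(confusion)
  present <- rs > 0
  if (!any(present)) stop("confusion matrix has no populated true class")
  if (!all(present))
    warning("excluding ", sum(!present), " empty true class(es) from the mean")
  mean(diag(confusion)[present] / rs[present])
}

#' Kruskal-Wallis comparison of two samples
#'
#' Rank-based test of whether two samples come from the same distribution:
#' the H statistic is computed from average ranks with the standard tie
#' correction and referred to the chi-square distribution with 1 degree of
#' freedom. When every pooled value is identical the statistic is 0 and the
#' p-value 1 (no evidence of a difference, not an error).
#'
#' @param a,b numeric samples, each non-empty, jointly of length >= 3.
#' @return list with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(pooled) < 3L) stop("need at least 3 values in total")
  if (all(pooled == pooled[1L])) return(list(statistic = 0, p.value = 1))
  kt <- stats::kruskal.test(list(a, b))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Cross-validated classification with one analysis arm
#'
#' Runs the discrete (`"pca_lda"`) or functional (`"fpca_lda"`) pipeline
#' under cross-validation. Within each fold, component models (PCA, or
#' B-spline approximation followed by FPCA) are fitted on the training
#' spectra only; the held-out spectra are projected into the training
#' component space (for the functional arm, test spectra are converted to
#' functions with the training basis — a fixed, data-independent knot
#' vector — and scored against the training FPCA model); LDA is fitted on
#' training scores and evaluated on the test scores. Per-spectrum
#' least-squares basis coefficients depend only on that spectrum, so they
#' are computed once and subset per fold; no test-fold information enters
#' any fitted model.
#'
#' @param spectra a [spectra_set()].
#' @param method `"pca_lda"` or `"fpca_lda"`.
#' @param n_components number of (functional) principal components kept.
#' @param folds optional precomputed folds from [make_folds()]; otherwise
#'   folds are built here from `scheme`, `k` and `seed`.
#' @param k,scheme,seed fold construction parameters (see [make_folds()]).
#' @param n_basis,order B-spline basis for the functional arm (study
#'   defaults: 190 cubic splines without background, 180 with).
#' @param center center functions in the FPCA step (default TRUE).
#' @param keep_models keep each fold's fitted component + LDA parameters
#'   (for audits); default FALSE.
#' @return object of class `cv_result`: list with `method`, `n_components`,
#'   `scheme`, `fold_confusion` (list of L x L matrices),
#'   `fold_sensitivity`, `mean_sensitivity`, `sd_sensitivity`, and
#'   optionally `models`.
#' @export
run_method_cv <- function(spectra, method = c("pca_lda", "fpca_lda"),
                          n_components = 50L, folds = NULL, k = 10L,
                          scheme = c("kfold", "lobo"), seed = 1L,
                          n_basis = 190L, order = 4L, center = TRUE,
                          keep_models = FALSE) {
  stopifnot(inherits(spectra, "spectra_set"))
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  labels <- spectra$labels
  classes <- sort(unique(labels))
  L <- length(classes)
  if (is.null(folds))
    folds <- make_folds(labels, k = k, scheme = scheme,
                        batches = spectra$batches, seed = seed)
  n_components <- as.integer(n_components)

  fd_all <- NULL
  if (method == "fpca_lda") {
    basis <- bspline_basis(range(spectra$grid), n_basis, order)
    fd_all <- fit_functional(spectra, basis)
  }

  nf <- length(folds)
  confusions <- vector("list", nf)
  sens <- numeric(nf)
  models <- if (keep_models) vector("list", nf)
  for (f in seq_len(nf)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    if (n_components > length(tr) - L)
      stop("fold ", f, ": n_components (", n_components,
           ") exceeds training size - L (", length(tr) - L, ")")
    if (method == "pca_lda") {
      comp <- spectra_pca(spectra$intensities[tr, , drop = FALSE], n_components)
      s_tr <- pca_scores(comp, spectra$intensities[tr, , drop = FALSE])
      s_te <- pca_scores(comp, spectra$intensities[te, , drop = FALSE])
      comp_params <- list(mean = comp$mean, loadings = comp$loadings,
                          eigenvalues = comp$eigenvalues)
    } else {
      comp <- fpca(fd_all[tr], n_components, center = center)
      s_tr <- fpca_scores(comp, fd_all[tr])
      s_te <- fpca_scores(comp, fd_all[te])
      comp_params <- list(mean = comp$mean_coefficients,
                          eigenfunctions = comp$eigenfunctions,
                          eigenvalues = comp$eigenvalues)
    }
    lmod <- lda_fit(s_tr, labels[tr])
    pred <- lda_predict(lmod, s_te)
    conf <- table(factor(labels[te], levels = classes),
                  factor(pred, levels = classes))
    confusions[[f]] <- unclass(conf)
    sens[f] <- mean_sensitivity(conf)
    if (keep_models)
      models[[f]] <- list(
        component = comp_params,
        lda = list(class_means = lmod$class_means,
                   within_scatter = lmod$within_scatter,
                   directions = lmod$directions, bias = lmod$bias)
      )
  }
  out <- list(method = method, n_components = n_components, scheme = scheme,
              fold_confusion = confusions, fold_sensitivity = sens,
              mean_sensitivity = mean(sens),
              sd_sensitivity = stats::sd(sens))
  if (keep_models) out$models <- models
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s, %d components, %s]: mean sensitivity %.3f +/- %.3f over %d folds\n",
              x$method, x$n_components, x$scheme, x$mean_sensitivity,
              x$sd_sensitivity, length(x$fold_sensitivity)))
  invisible(x)
}

#' Compare both analysis arms over a simulation grid
#'
#' For every simulation configuration: generate the dataset, build one set
#' of stratified folds shared by both arms, run [run_method_cv()] with
#' `"pca_lda"` and `"fpca_lda"`, and test the difference of the two arms'
#' per-fold mean sensitivities with [kruskal_wallis()]. A cell that fails
#' is recorded as `NA` rather than aborting the grid.
#'
#' @param configs list of [raman_sim_config()] objects (for the study
#'   design, [simulation_grid()]).
#' @param n_components components per arm (study default 50).
#' @param n_basis,order functional-arm basis (study defaults: 190 cubic
#'   splines without background, 180 with background).
#' @param k folds (study default 10).
#' @param verbose print one line per completed cell.
#' @return object of classes `comparison_grid`/`data.frame` with columns
#'   `shift`, `snr`, `sens_pca`, `sd_pca`, `sens_fpca`, `sd_fpca`, `diff`
#'   (fpca - pca) and `kw_p`.
#' @export
run_grid_comparison <- function(configs, n_components = 50L, n_basis = 190L,
                                order = 4L, k = 10L, verbose = FALSE) {
  rows <- lapply(configs, function(cfg) {
    res <- tryCatch({
      sim <- simulate_raman(cfg)
      folds <- make_folds(sim$labels, k = k, seed = cfg$seed)
      r_pca <- run_method_cv(sim, "pca_lda", n_components, folds = folds)
      r_fpca <- run_method_cv(sim, "fpca_lda", n_components, folds = folds,
                              n_basis = n_basis, order = order)
      kw <- kruskal_wallis(r_pca$fold_sensitivity, r_fpca$fold_sensitivity)
      data.frame(shift = cfg$shift, snr = cfg$snr,
                 sens_pca = r_pca$mean_sensitivity,
                 sd_pca = r_pca$sd_sensitivity,
                 sens_fpca = r_fpca$mean_sensitivity,
                 sd_fpca = r_fpca$sd_sensitivity,
                 diff = r_fpca$mean_sensitivity - r_pca$mean_sensitivity,
                 kw_p = kw$p.value)
    }, error = function(e) {
      warning("grid cell (shift = ", cfg$shift, ", snr = ", cfg$snr,
              ") failed: ", conditionMessage(e), call. = FALSE)
      data.frame(shift = cfg$shift, snr = cfg$snr, sens_pca = NA_real_,
                 sd_pca = NA_real_, sens_fpca = NA_real_, sd_fpca = NA_real_,
                 diff = NA_real_, kw_p = NA_real_)
    })
    if (verbose)
      message(sprintf("shift %.3f snr %5.1f: pca %.3f fpca %.3f",
                      res$shift, res$snr, res$sens_pca, res$sens_fpca))
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_grid", "data.frame")
  out
}
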