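#' Spectra collection on a shared grid
#'
#' The package's discrete data container: `N` spectra measured on a common
#' strictly increasing `p`-point axis, with one class label per spectrum and
#' optional batch labels (used by leave-one-batch-out cross-validation).
#'
#' @param intensities numeric `N x p` matrix, one spectrum per row; all
#'   entries must be finite.
#' @param grid numeric length-`p` strictly increasing axis; default equally
#'   spaced on `[0, 1]`.
#' @param labels character/factor length `N` of class labels.
#' @param batches optional length-`N` batch labels.
#' @return An object of class `spectra_set`: list with `intensities`,
#'   `grid`, `labels`, `batches`.
#' @export
spectra_set <- function(intensities, grid = NULL, labels, batches = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (n < 1L || p < 2L) stop("need at least 1 spectrum with at least 2 points")
  if (!all(is.finite(intensities))) stop("all intensities must be finite")
  if (is.null(grid)) grid <- seq(0, 1, length.out = p)
  grid <- as.numeric(grid)
  if (length(grid) != p) stop("`grid` length must equal ncol(intensities)")
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing")
  labels <- as.character(labels)
  if (length(labels) != n) stop("`labels` length must equal nrow(intensities)")
  if (!is.null(batches)) {
    batches <- as.character(batches)
    if (length(batches) != n) stop("`batches` length must equal nrow(intensities)")
  }
  structure(
    list(intensities = intensities, grid = grid, labels = labels,
         batches = batches),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", nrow(x$intensities), "spectra x",
      ncol(x$intensities), "points\n")
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$labels)),
                                  table(x$labels)), collapse = ", "), "\n")
  if (!is.null(x$batches))
    cat("  batches:", paste(unique(x$batches), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a spectra_set by row
#'
#' @param x a `spectra_set`.
#' @param i row (spectrum) indices.
#' @param ... unused.
#' @return a `spectra_set` holding the selected spectra.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  out <- spectra_set(x$intensities[i, , drop = FALSE], x$grid,
                     x$labels[i],
                     if (!is.null(x$batches)) x$batches[i])
  if (!is.null(attr(x, "clean")))
    attr(out, "clean") <- attr(x, "clean")[i, , drop = FALSE]
  out
}
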