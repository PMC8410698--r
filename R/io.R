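#' Write spectra to delimited text
#'
#' One row per spectrum: first column the class label, then (if present) a
#' `batch` column, then the `p` intensity values. The header row carries the
#' literal column names `label` (and `batch`) followed by the grid values,
#' so the axis round-trips with the data. If `config` is supplied, the full
#' simulation configuration is written as a JSON sidecar at
#' `paste0(path, ".json")`.
#'
#' @param spectra a [spectra_set()].
#' @param path output CSV path.
#' @param config optional [raman_sim_config()] to record alongside.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, config = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  has_batch <- !is.null(spectra$batches)
  header <- c("label", if (has_batch) "batch",
              formatC(spectra$grid, format = "g", digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  vals <- formatC(spectra$intensities, format = "g", digits = 17)
  for (i in seq_len(nrow(spectra$intensities))) {
    row <- c(spectra$labels[i], if (has_batch) spectra$batches[i], vals[i, ])
    writeLines(paste(row, collapse = ","), con)
  }
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read spectra from delimited text
#'
#' Inverse of [write_spectra()]. The first column must be the class label;
#' a second column named `batch` (in the header) is read as batch labels.
#' With `grid_header = TRUE` (default) the remaining header fields are
#' parsed as the numeric axis; with `grid_header = FALSE` the file has no
#' header and the axis defaults to equally spaced points on `[0, 1]`.
#' Ragged rows and non-numeric intensities raise errors naming the
#' offending row.
#'
#' @param path CSV path.
#' @param grid_header logical; whether the first line is a header carrying
#'   grid values.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, grid_header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  ragged <- which(nf != nf[1L])
  if (length(ragged) > 0L)
    stop("ragged row(s) ", paste(utils::head(ragged, 5L), collapse = ", "),
         ": expected ", nf[1L], " fields")
  has_batch <- FALSE
  if (grid_header) {
    hdr <- fields[[1L]]
    if (hdr[1L] != "label")
      stop("header must start with `label` (got `", hdr[1L], "`)")
    has_batch <- length(hdr) >= 2L && hdr[2L] == "batch"
    n_meta <- if (has_batch) 2L else 1L
    grid <- suppressWarnings(as.numeric(hdr[-seq_len(n_meta)]))
    if (anyNA(grid)) stop("header grid values are not numeric")
    data_lines <- fields[-1L]
  } else {
    n_meta <- 1L
    grid <- NULL
    data_lines <- fields
  }
  if (length(data_lines) == 0L) stop("no data rows in ", path)
  p <- nf[1L] - n_meta
  if (p < 2L) stop("need at least 2 intensity columns")
  labels <- vapply(data_lines, `[`, character(1), 1L)
  batches <- if (has_batch) vapply(data_lines, `[`, character(1), 2L)
  intensities <- matrix(NA_real_, length(data_lines), p)
  for (i in seq_along(data_lines)) {
    v <- suppressWarnings(as.numeric(data_lines[[i]][-seq_len(n_meta)]))
    if (anyNA(v))
      stop("non-numeric intensity in data row ", i)
    intensities[i, ] <- v
  }
  if (is.null(grid)) grid <- seq(0, 1, length.out = p)
  spectra_set(intensities, grid, labels, batches)
}

#' Write a grid-comparison table to CSV
#'
#' Fixed column order `shift, snr, sens_pca, sd_pca, sens_fpca, sd_fpca,
#' diff, kw_p`; failed (missing) cells appear as empty fields.
#'
#' @param grid a [run_grid_comparison()] result (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_results <- function(grid, path) {
  cols <- c("shift", "snr", "sens_pca", "sd_pca", "sens_fpca", "sd_fpca",
            "diff", "kw_p")
  df <- as.data.frame(grid)[, cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a grid-comparison table written by [write_grid_results()]
#'
#' @param path CSV path.
#' @return a `comparison_grid` data frame.
#' @export
read_grid_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("comparison_grid", "data.frame")
  df
}
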