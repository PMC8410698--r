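#' Configuration for the two-class Raman simulator
#'
#' Describes one simulated dataset: a "normal" class built from a few
#' Gaussian bands on a normalized spectral axis, and an "abnormal" class
#' identical except that one band is translated by `shift`. Additive white
#' Gaussian noise is scaled so that the ratio of the tallest clean band to
#' the noise standard deviation equals `snr`; optionally every spectrum also
#' receives its own random smooth quadratic background.
#'
#' The defaults describe three well-separated bands at 0.25, 0.50 and 0.75
#' with widths 0.01, 0.015, 0.01 and amplitudes 1.0, 0.8, 0.6; the middle
#' band is the one shifted in the abnormal class. Shift values are positions
#' on the normalized `[0, 1]` axis.
#'
#' @param shift non-negative translation of the shifted band (normalized
#'   axis units); the study grid uses 0.001, 0.003, 0.005, 0.01, 0.02,
#'   0.025, 0.05.
#' @param snr target signal-to-noise ratio (> 0): tallest clean band
#'   amplitude divided by the noise standard deviation; the study grid uses
#'   0.5, 1, 2, 3, 5, 10, 30, 50, 100.
#' @param n_per_class spectra per class (default 100).
#' @param n_points pixels per spectrum (default 1024).
#' @param peak_positions,peak_widths,peak_amplitudes Gaussian band centers
#'   (in `[0, 1]`), standard-deviation widths (> 0) and heights (> 0).
#' @param shifted_peak 1-based index of the band that moves in the abnormal
#'   class.
#' @param background logical; add a per-spectrum random quadratic baseline.
#' @param bg_max_range range (as multiples of the tallest band amplitude)
#'   from which each background's maximum height is drawn uniformly.
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration including this seed.
#' @return an object of class `raman_sim_config` (a validated list).
#' @export
raman_sim_config <- function(shift = 0.05, snr = 30,
                             n_per_class = 100L, n_points = 1024L,
                             peak_positions = c(0.25, 0.50, 0.75),
                             peak_widths = c(0.010, 0.015, 0.010),
                             peak_amplitudes = c(1.0, 0.8, 0.6),
                             shifted_peak = 2L,
                             background = FALSE,
                             bg_max_range = c(0.5, 2),
                             seed = 1L) {
  if (!is.finite(snr) || snr <= 0) stop("`snr` must be > 0")
  if (!is.finite(shift) || shift < 0) stop("`shift` must be >= 0")
  np <- length(peak_positions)
  if (np < 1L || length(peak_widths) != np || length(peak_amplitudes) != np)
    stop("peak position/width/amplitude vectors must have equal length >= 1")
  if (any(peak_widths <= 0) || any(peak_amplitudes <= 0))
    stop("peak widths and amplitudes must be strictly positive")
  if (any(peak_positions < 0) || any(peak_positions > 1))
    stop("peak positions must lie in [0, 1]")
  shifted_peak <- as.integer(shifted_peak)
  if (shifted_peak < 1L || shifted_peak > np)
    stop("`shifted_peak` must index a peak")
  if (peak_positions[shifted_peak] + shift > 1)
    stop("shifted peak would leave the [0, 1] domain (position ",
         peak_positions[shifted_peak], " + shift ", shift, " > 1)")
  n_per_class <- as.integer(n_per_class)
  n_points <- as.integer(n_points)
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1")
  if (n_points < 2L) stop("`n_points` must be >= 2")
  if (length(bg_max_range) != 2L || bg_max_range[1] < 0 ||
      bg_max_range[2] < bg_max_range[1])
    stop("`bg_max_range` must be an increasing non-negative pair")
  structure(
    list(shift = shift, snr = snr, n_per_class = n_per_class,
         n_points = n_points, peak_positions = as.numeric(peak_positions),
         peak_widths = as.numeric(peak_widths),
         peak_amplitudes = as.numeric(peak_amplitudes),
         shifted_peak = shifted_peak, background = isTRUE(background),
         bg_max_range = as.numeric(bg_max_range), seed = as.integer(seed)),
    class = "raman_sim_config"
  )
}

# sum of Gaussian bands a * exp(-(t - mu)^2 / (2 w^2)) on the grid
gaussian_bands <- function(grid, positions, widths, amplitudes) {
  y <- numeric(length(grid))
  for (j in seq_along(positions)) {
    y <- y + amplitudes[j] * exp(-(grid - positions[j])^2 / (2 * widths[j]^2))
  }
  y
}

#' Random smooth quadratic backgrounds
#'
#' Draws `n` independent baselines of the form `b0 + b1 t + b2 t^2`,
#' rejected until non-negative on `[0, 1]` and then rescaled so each
#' baseline's maximum is uniform on `max_range * peak_max`. This is the
#' conventional low-order-polynomial stand-in for a Raman fluorescence
#' baseline: smooth and broad compared to any vibrational band.
#'
#' @param n number of backgrounds.
#' @param grid evaluation axis in `[0, 1]`.
#' @param peak_max reference amplitude (tallest band of the clean signal).
#' @param max_range multiplier range for the background maximum.
#' @return `n x length(grid)` matrix of background curves.
#' @export
random_background <- function(n, grid, peak_max = 1, max_range = c(0.5, 2)) {
  out <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    repeat {
      b0 <- stats::runif(1, 0, 1)
      b1 <- stats::runif(1, -1, 1)
      b2 <- stats::runif(1, -1, 1)
      # exact minimum of the quadratic on [0, 1]: endpoints plus vertex
      cand <- c(0, 1)
      if (b2 != 0) {
        v <- -b1 / (2 * b2)
        if (v > 0 && v < 1) cand <- c(cand, v)
      }
      qv <- b0 + b1 * cand + b2 * cand^2
      if (min(qv) >= 0 && max(qv) > 0) break
    }
    q <- b0 + b1 * grid + b2 * grid^2
    m <- stats::runif(1, max_range[1], max_range[2]) * peak_max
    out[i, ] <- q * (m / max(qv))
  }
  out
}

#' Simulate a two-class Raman dataset
#'
#' Generates `2 * n_per_class` spectra on `n_points` equally spaced pixels
#' over the normalized axis `[0, 1]`. Normal spectra are the sum of the
#' configured Gaussian bands plus i.i.d. Gaussian noise with standard
#' deviation `max(clean signal) / snr`; abnormal spectra are identical
#' except the designated band is translated by `+shift`. With
#' `background = TRUE` each spectrum additionally receives its own random
#' quadratic baseline (see [random_background()]).
#'
#' The known noise-free component of every spectrum (bands plus its own
#' background, if any) is kept in the `"clean"` attribute of the result so
#' denoising performance can be measured against ground truth.
#'
#' @param config a [raman_sim_config()].
#' @return a [spectra_set()] with labels `"normal"` / `"abnormal"`, the
#'   generating `config` in attribute `"config"` and the noise-free signal
#'   matrix in attribute `"clean"`.
#' @export
simulate_raman <- function(config = raman_sim_config()) {
  stopifnot(inherits(config, "raman_sim_config"))
  set.seed(config$seed)
  grid <- seq(0, 1, length.out = config$n_points)
  clean_normal <- gaussian_bands(grid, config$peak_positions,
                                 config$peak_widths, config$peak_amplitudes)
  pos_ab <- config$peak_positions
  pos_ab[config$shifted_peak] <- pos_ab[config$shifted_peak] + config$shift
  clean_abnormal <- gaussian_bands(grid, pos_ab, config$peak_widths,
                                   config$peak_amplitudes)
  amax <- max(clean_normal)
  sd_noise <- amax / config$snr
  n <- config$n_per_class
  p <- config$n_points
  clean <- rbind(
    matrix(clean_normal, n, p, byrow = TRUE),
    matrix(clean_abnormal, n, p, byrow = TRUE)
  )
  noise <- matrix(stats::rnorm(2L * n * p, sd = sd_noise), 2L * n, p)
  if (config$background) {
    bg <- random_background(2L * n, grid, peak_max = amax,
                            max_range = config$bg_max_range)
    clean <- clean + bg
  }
  labels <- rep(c("normal", "abnormal"), each = n)
  out <- spectra_set(clean + noise, grid, labels)
  attr(out, "config") <- config
  attr(out, "clean") <- clean
  out
}

#' The full peak-shift by signal-to-noise study grid
#'
#' Returns the Cartesian product of the 7 study peak shifts (0.001, 0.003,
#' 0.005, 0.01, 0.02, 0.025, 0.05) and 9 signal-to-noise ratios (0.5, 1, 2,
#' 3, 5, 10, 30, 50, 100): 63 simulation configurations of 200 spectra
#' (100 per class, 1024 pixels) each. Per-case sub-seeds are drawn once from
#' a generator seeded with `seed`, so the cases are mutually independent yet
#' each individually reproducible in any order.
#'
#' @param seed master integer seed.
#' @param background logical, passed to every configuration.
#' @param n_per_class,n_points per-case sizes (study defaults 100 and 1024).
#' @param shifts,snrs the grid axes; defaults are the study values.
#' @return list of 63 [raman_sim_config()] objects, shift varying slowest.
#' @export
simulation_grid <- function(seed = 1L, background = FALSE,
                            n_per_class = 100L, n_points = 1024L,
                            shifts = c(0.001, 0.003, 0.005, 0.01, 0.02,
                                       0.025, 0.05),
                            snrs = c(0.5, 1, 2, 3, 5, 10, 30, 50, 100)) {
  set.seed(as.integer(seed))
  n_case <- length(shifts) * length(snrs)
  sub_seeds <- sample.int(.Machine$integer.max, n_case)
  configs <- vector("list", n_case)
  i <- 0L
  for (sh in shifts) {
    for (sn in snrs) {
      i <- i + 1L
      configs[[i]] <- raman_sim_config(
        shift = sh, snr = sn, n_per_class = n_per_class,
        n_points = n_points, background = background, seed = sub_seeds[i]
      )
    }
  }
  configs
}

#' Add random quadratic backgrounds to existing spectra
#'
#' Adds an independent smooth quadratic baseline (see [random_background()])
#' to every spectrum. Grid and labels are unchanged. `scale = 0` returns the
#' input intensities untouched.
#'
#' @param spectra a [spectra_set()].
#' @param peak_max reference amplitude for the background height; default is
#'   the maximum observed intensity.
#' @param max_range multiplier range for the per-spectrum background maximum.
#' @param scale overall multiplier applied to the generated backgrounds.
#' @param seed optional seed for the background draws.
#' @return a `spectra_set` with backgrounds added.
#' @export
add_background <- function(spectra, peak_max = NULL, max_range = c(0.5, 2),
                           scale = 1, seed = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (scale == 0) return(spectra)
  if (is.null(peak_max)) peak_max <- max(abs(spectra$intensities))
  bg <- scale * random_background(nrow(spectra$intensities), spectra$grid,
                                  peak_max = peak_max, max_range = max_range)
  out <- spectra_set(spectra$intensities + bg, spectra$grid,
                     spectra$labels, spectra$batches)
  if (!is.null(attr(spectra, "clean")))
    attr(out, "clean") <- attr(spectra, "clean") + bg
  attr(out, "config") <- attr(spectra, "config")
  out
}

#' Estimate the signal-to-noise ratio of a measured spectrum
#'
#' The ratio of the intensity at the grid point nearest `peak_position` to
#' the sample standard deviation over a signal-free ("silent") region of the
#' axis. This mirrors the conventional experimental estimate: C-H band
#' amplitude over the standard deviation of the silent region of the
#' spectrum.
#'
#' @param spectrum numeric intensity vector.
#' @param grid axis values, same length as `spectrum`.
#' @param peak_position axis location of the reference band.
#' @param silent_region length-2 axis interval containing at least 3 grid
#'   points and no signal.
#' @return the scalar SNR estimate.
#' @export
estimate_snr <- function(spectrum, grid, peak_position, silent_region) {
  spectrum <- as.numeric(spectrum)
  grid <- as.numeric(grid)
  if (length(spectrum) != length(grid))
    stop("`spectrum` and `grid` lengths differ")
  if (peak_position < min(grid) || peak_position > max(grid))
    stop("`peak_position` outside the grid")
  if (length(silent_region) != 2L)
    stop("`silent_region` must be a length-2 interval")
  idx <- which(grid >= min(silent_region) & grid <= max(silent_region))
  if (length(idx) < 3L)
    stop("silent region must contain at least 3 grid points")
  s <- stats::sd(spectrum[idx])
  if (!is.finite(s) || s == 0)
    stop("silent region has zero variance; SNR undefined")
  peak <- spectrum[which.min(abs(grid - peak_position))]
  peak / s
}
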