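---
title: "Functional versus discrete analysis of Raman spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional versus discrete analysis of Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfda)
```

This vignette records the models behind `specfda` and, more importantly,
the design decisions taken where a choice was genuinely open: a comparison
of two analysis regimes is only meaningful if every convention shared by
the two arms is pinned down explicitly.

## The two analysis arms

Both arms classify `N` spectra sampled on a common `p`-point grid into `L`
classes via component scores and linear discriminant analysis.

**Discrete arm (PCA-LDA).** Scores are projections of the mean-centered
intensity vectors onto the leading eigenvectors of the sample covariance
matrix. We use the population (`1/N`) covariance normalization in both
arms, so eigenvalues are directly comparable; the loadings are computed
through the thin SVD of the centered data matrix, which is algebraically
identical to the covariance eigenproblem and cheaper when `N << p`.

**Functional arm (FPCA-LDA).** Each spectrum is first approximated as
`x_i(t) = sum_k c_ik phi_k(t)` in a clamped B-spline basis by least
squares (QR decomposition of the grid-evaluated basis matrix; the
normal-equations form exists in the test suite only, as an oracle).
FPCA then solves the covariance-operator eigenproblem exactly in
coefficient space: with Gram matrix `W` (`W_kl = integral phi_k phi_l`)
and centered coefficients `C`, the symmetric eigenproblem of
`(1/N) W^{1/2} C'C W^{1/2}` yields eigenvalues `rho_j` and, after the
back-map `b_j = W^{-1/2} u_j`, eigenfunction coefficient vectors that are
orthonormal in the L2 inner product. Scores are `f_ij = (C_i - mean)' W b_j`.
We chose the coefficient-space route over dense-grid discretization because
the Gram matrix is exact for piecewise polynomials (per-span Gauss–Legendre
with `O` nodes, exact for the degree `2O-2` integrand), so the only
approximation in the functional arm is the basis expansion itself; the
dense-grid quadrature PCA survives as an independent test oracle.
An operator built from `N` centered functions has rank at most `N - 1`,
and the implementation enforces `m <= min(K, N - 1)` components.

**Centering.** A covariance function can be written without mean
subtraction, but the maximum-variance characterization of principal
components presupposes centered data, and classical PCA practice centers.
`fpca(center = TRUE)` is therefore the default; `center = FALSE`
diagonalizes the raw second-moment operator for users who want the
literal uncentered form.

**LDA.** Between-class scatter `B = sum_l n_l (mean_l - mean)(...)'` and
within-class scatter `W_s` as the pooled per-member scatter (the
per-member sum is the only dimensionally consistent reading). The
generalized eigenproblem `W_s^{-1} B` is solved by Cholesky whitening of
`W_s` plus a symmetric eigensolve — stable, and it fails loudly (rather
than silently regularizing) when `W_s` is singular, which signals more
components than the training folds can support; `ridge` is an explicit
escape hatch. Since no assignment rule is implied by the discriminant
functions alone, prediction uses the equal-prior linear Gaussian rule:
nearest class mean in Mahalanobis distance under the pooled within-class
covariance. Equal priors fit the balanced two-class simulations; ties
resolve to the lexicographically smallest label. The bias `b_0` is
`-Omega %*% overall_mean`, centering the discriminant coordinates.

## The simulator

The simulator emulates the canonical two-group biomedical situation where
one vibrational band moves slightly between groups (e.g. a protein
secondary-structure change or isotope labeling):

* **Axis.** Abstract normalized wavenumber axis `[0, 1]`, `p = 1024`
  equally spaced pixels including both endpoints. The study's shift values
  (0.001–0.05) are read as distances on this unit axis.
* **Line shape.** Gaussian profiles `a exp(-(t-mu)^2 / (2w^2))` — the
  standard choice for simulated Raman bands. Defaults: centers
  (0.25, 0.50, 0.75), widths (0.010, 0.015, 0.010), amplitudes
  (1.0, 0.8, 0.6), and the middle band is the one shifted. Three
  well-separated bands of unequal height on a unit axis are a realistic
  minimal spectrum; every parameter is overridable in
  `raman_sim_config()`.
* **Noise and SNR.** i.i.d. additive Gaussian noise per pixel with
  standard deviation `max(clean signal) / SNR`. This matches the
  experimental SNR estimator implemented in `estimate_snr()` (band
  amplitude over the standard deviation of a signal-free region), so the
  simulation's "SNR = 10" means what a spectroscopist would measure.
* **Background.** "Random background" is modelled as a per-spectrum
  quadratic `b0 + b1 t + b2 t^2`, rejection-sampled to be non-negative on
  the domain and rescaled so its maximum is uniform on 0.5–2 times the
  tallest band. A low-order polynomial is the conventional stand-in for a
  broad fluorescence baseline: smooth (its curvature is orders of
  magnitude below any band's) yet varying spectrum to spectrum.
* **Reproducibility.** A dataset is a pure function of its configuration
  including the seed. `simulation_grid()` draws one sub-seed per grid cell
  from a generator seeded with the master seed, so the 63 cases are
  mutually independent and each reproducible in isolation.

What the simulator deliberately does **not** emulate: cosmic-ray spikes,
detector etaloning, wavenumber-calibration error, and
heteroscedastic/Poisson photon noise. Conclusions drawn from passing tests
therefore concern the additive-Gaussian, fixed-grid regime; real spectra
add artifacts whose interaction with the basis expansion is untested here.

## Choosing the basis size

`select_nbasis_elbow()` computes, for each candidate `K`, the
root-mean-square error of the basis reconstruction pooled over all spectra
and pixels (per-spectrum and pooled averaging coincide on a shared grid),
then picks the candidate farthest from the chord joining the first and
last `(K, RMSE)` points. Two conventions are ours: both axes are min–max
normalized first, because `K` (tens to hundreds) and RMSE (typically well
below 1) are incommensurate and the chord distance is otherwise dominated
by one axis; and ties — including an exactly linear curve — resolve to the
smallest `K`, the more parsimonious model. One `K` is selected per
dataset, not per spectrum. The default candidate grid 10–300 (step 10)
brackets the basis sizes that matter for 1024-pixel spectra.

For the comparison harness, the basis size is fixed per run (190 cubic
splines for background-free simulations, 180 with background, selections
supported by the elbow curve) rather than re-selected inside each
cross-validation fold. Since the knot vector is data-independent given
`K`, this costs no test-set purity for a fixed run; re-running the elbow
per fold is available to the strict by passing per-fold data to
`select_nbasis_elbow()` directly.

## B-spline conventions

The Cox–de Boor recursion as usually printed leaves three details open;
`specfda` fixes them as follows. (1) Any recursion term with a zero
denominator — unavoidable with the repeated knots of a clamped vector —
is defined as zero. (2) The order-1 functions are indicators of the
half-open spans `[t_k, t_{k+1})`, closed at the right domain endpoint so
the final pixel is representable and the partition of unity holds on the
closed domain. (3) Interior knots are equally spaced (no placement rule
is canonical for spectra on a uniform grid; quantile placement is not
implemented). Note the package indexes knots from 1 in R convention;
a knot vector of `K + O` entries supports `K` order-`O` functions.

## Cross-validation harness

* **Folds.** Stratified k-fold (class proportions within one member) —
  unstratified folds can starve a class at small `n`; or leave-one-batch-out,
  one fold per batch, for batched experimental data.
* **Test-fold handling.** Component models are fitted on training folds
  only; test spectra are projected into the training component space. For
  the functional arm the test spectra are converted to functions by least
  squares against the training basis (fixed knots), then scored against
  the training FPCA model. Per-spectrum coefficients depend only on that
  spectrum, so they are computed once and subset per fold — numerically
  identical to refitting within each fold, with no information flow.
* **Metric.** Mean sensitivity: per-class recall averaged over classes,
  then over folds; the quoted spread is the standard deviation across
  folds of one cross-validation run.
* **Method comparison.** Per grid cell, the Kruskal–Wallis test compares
  the two arms' per-fold mean sensitivities (k + k values, the two arms
  sharing the same folds), with the standard tie correction and the
  chi-square reference with one degree of freedom. If every pooled value
  is identical — common when both arms are perfect — the statistic is 0
  and the p-value 1 by convention.

## Numerical choices and degenerate inputs

* Eigenfunction/loading signs are normalized (largest-magnitude
  coefficient positive) so outputs are identical across LAPACK builds.
* `W^{1/2}` uses the symmetric eigendecomposition of the Gram matrix with
  eigenvalues floored at 1e-12; for the clamped bases used here `W` is
  comfortably positive definite.
* Rank-deficient least-squares designs, out-of-domain evaluation points,
  dimension mismatches, `m > N - 1`, singular within-class scatter, and
  sub-3-point silent regions in `estimate_snr()` all raise immediate,
  specific errors rather than degrading silently.
* A failed cell in `run_grid_comparison()` is recorded as `NA` with a
  warning, so a 63-cell run survives one pathological cell.

## Problem sizes in the test suite

Unit tests run on reduced data (tens of spectra, 40–256 pixels, `K` up to
40) where the properties under test are scale-free; the end-to-end checks
use the full study geometry — 200 × 1024 datasets, 190/180 basis
functions, 50 components, 10-fold cross-validation — at a handful of grid
cells chosen to pin the qualitative regime structure (perfect separation
at high SNR and large shift; chance level under label permutation; the
denoising advantage at SNR 0.5). A full 63-cell comparison is a single
`run_grid_comparison(simulation_grid(seed), ...)` call away and completes
in well under an hour on one core.

## Known limitations

* The functional arm's advantage is sensitive to the basis size: too
  large refits the noise, too small erases narrow bands. The elbow method
  is a heuristic, and on experimental data a domain-driven override (as
  `n_basis` everywhere allows) can be preferable.
* Smoothing here is purely by basis truncation; roughness-penalized
  (P-spline) fitting and penalized FPCA are out of scope.
* Fourier bases (for periodic data), sparse/irregular longitudinal FPCA,
  quadratic/shrinkage discriminants, and class-frequency priors are not
  implemented.
* The CSV interchange format is deliberately minimal; spectroscopy
  container formats (SPC, JCAMP-DX) are out of scope.
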