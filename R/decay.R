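#' Build a discrete Gaussian instrument response function
#'
#' Samples a Gaussian of the requested full width at half maximum at the TCSPC
#' bin centres and normalizes it to unit area. The numerically measured FWHM
#' of the returned curve is within one bin width of the request.
#'
#' @param fwhm_ps Full width at half maximum, picoseconds (> 0).
#' @param bin_width_ps TCSPC bin width, picoseconds.
#' @param n_bins Number of time bins.
#' @param center_ps Position of the pulse peak (default places the whole
#'   pulse comfortably inside the window).
#' @return An object of class `irf`: `curve` (length `n_bins`, sums to 1),
#'   bin grid and pulse parameters.
#' @export
make_irf <- function(fwhm_ps, bin_width_ps = 48.8, n_bins = 256,
                     center_ps = max(5 * fwhm_ps / 2.354820045, 3 * bin_width_ps)) {
  if (fwhm_ps <= 0) stop("fwhm_ps must be > 0", call. = FALSE)
  if (bin_width_ps <= 0) stop("bin_width_ps must be > 0", call. = FALSE)
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  window <- n_bins * bin_width_ps
  if (center_ps + 4 * sigma > window)
    stop("n_bins too small to contain the IRF pulse", call. = FALSE)
  t_ps <- (seq_len(n_bins) - 0.5) * bin_width_ps
  curve <- exp(-0.5 * ((t_ps - center_ps) / sigma)^2)
  curve <- curve / sum(curve)
  structure(list(curve = curve, t_ps = t_ps, bin_width_ps = bin_width_ps,
                 n_bins = as.integer(n_bins), fwhm_ps = fwhm_ps,
                 center_ps = center_ps), class = "irf")
}

#' Numerically measure the FWHM of a sampled curve
#'
#' Linear interpolation of the half-maximum crossings on either side of the
#' peak; used to verify IRF construction.
#'
#' @param curve Sampled non-negative curve.
#' @param bin_width Grid spacing (the result is in the same units).
#' @return The full width at half maximum.
#' @export
measure_fwhm <- function(curve, bin_width = 1) {
  pk <- which.max(curve)
  half <- curve[pk] / 2
  cross <- function(idx) {
    i <- idx[which(curve[idx] >= half)[1]]
    if (is.na(i) || i == idx[1]) return((idx[1] - 0.5))
    j <- idx[match(i, idx) - 1]   # last below-half sample before the crossing
    frac <- (half - curve[j]) / (curve[i] - curve[j])
    j + frac * (i - j) - 0.5
  }
  left <- cross(seq_len(pk))
  right_rev <- cross(rev(pk:length(curve)))
  (right_rev - left) * bin_width
}

#' IRF-convolved bi-exponential decay model
#'
#' Expected TCSPC counts per bin for the two-component NAD(P)H decay
#' `a1 * exp(-t/t1) + (1 - a1) * exp(-t/t2)` convolved (linear, discrete) with
#' the instrument response function, then normalized over the acquisition
#' window and scaled to the requested total. `t1` and `t2` are the short
#' (free NAD(P)H) and long (protein-bound NAD(P)H) lifetime components.
#'
#' @param a1 Fractional amplitude of the short component, in \[0, 1\];
#'   `a2 = 1 - a1`.
#' @param t1_ns,t2_ns Short and long lifetimes, nanoseconds, `0 < t1 < t2`.
#' @param scale Expected total counts over the window.
#' @param irf An [make_irf()] object (or any list with `curve` and
#'   `bin_width_ps`).
#' @param n_bins Number of bins; defaults to the IRF grid.
#' @return Numeric vector of expected counts per bin (sums to `scale`).
#' @export
model_decay <- function(a1, t1_ns, t2_ns, scale = 1, irf,
                        n_bins = length(irf$curve)) {
  if (a1 < 0 || a1 > 1) stop("a1 must be in [0, 1]", call. = FALSE)
  if (t1_ns <= 0 || t2_ns <= 0) stop("lifetimes must be positive", call. = FALSE)
  if (n_bins != length(irf$curve))
    stop("bin grid does not match the IRF grid", call. = FALSE)
  t_ns <- (seq_len(n_bins) - 0.5) * irf$bin_width_ps / 1000
  d <- a1 * exp(-t_ns / t1_ns) + (1 - a1) * exp(-t_ns / t2_ns)
  y <- convolve_linear(irf$curve, d)
  scale * y / sum(y)
}

# First n terms of the linear (open) convolution of two equal-length vectors.
convolve_linear <- function(a, b) {
  n <- length(a)
  stats::convolve(a, rev(b), type = "open")[seq_len(n)]
}

#' Simulate one TCSPC decay histogram
#'
#' Poisson counts around the IRF-convolved bi-exponential model scaled to a
#' total-photon expectation; `noiseless = TRUE` returns the expectation
#' itself (identical to [model_decay()]).
#'
#' @inheritParams model_decay
#' @param total_photons Expected total photon count (> 0).
#' @param seed Integer seed.
#' @param noiseless Return the expected counts instead of a Poisson draw.
#' @return A `decay_histogram`: integer (or expected) `counts`, the IRF and
#'   bin width.
#' @export
simulate_decay <- function(a1, t1_ns, t2_ns, total_photons, irf,
                           n_bins = length(irf$curve), seed = NULL,
                           noiseless = FALSE) {
  if (total_photons <= 0) stop("total_photons must be > 0", call. = FALSE)
  lam <- model_decay(a1, t1_ns, t2_ns, scale = total_photons, irf = irf,
                     n_bins = n_bins)
  counts <- if (noiseless) lam else
    with_local_seed(seed, rpois(length(lam), lam))
  structure(list(counts = counts, irf = irf,
                 bin_width_ps = irf$bin_width_ps,
                 truth = c(a1 = a1, t1 = t1_ns, t2 = t2_ns)),
            class = "decay_histogram")
}
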