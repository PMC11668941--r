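#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, the standard "canonical" HRF shape:
#' a positive response peaking at `peak` seconds minus an undershoot peaking
#' at `undershoot` seconds scaled by `1/ratio`. The kernel is normalised to a
#' maximum of 1 so that a regressor built from a unit boxcar carries the
#' stimulus amplitude unchanged (betas stay in percent-signal units).
#'
#' @param t Time points in seconds at which to sample the kernel (>= 0).
#' @param peak Time-to-peak of the positive lobe, seconds.
#' @param undershoot Time-to-peak of the undershoot lobe, seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of kernel values, max 1.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stopifnot(all(t >= 0), peak > 0, undershoot > peak, ratio > 0)
  # gamma density with rate 1 has mode shape-1, so shape = peak + 1
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  h / max(h)
}

#' Sample the canonical HRF at the repetition time
#'
#' @param tr_s Repetition time in seconds.
#' @param duration_s Kernel support in seconds (default 32, covering the
#'   undershoot recovery).
#' @param peak,undershoot,ratio Passed to [canonical_hrf()].
#' @return Numeric kernel sampled at `0, tr_s, 2*tr_s, ...`.
#' @export
hrf_kernel <- function(tr_s, duration_s = 32, peak = 6, undershoot = 16,
                       ratio = 6) {
  canonical_hrf(seq(0, duration_s, by = tr_s), peak = peak,
                undershoot = undershoot, ratio = ratio)
}

# Causal convolution of a frame-sampled regressor with a kernel, truncated to
# the run length.
convolve_regressor <- function(x, kernel) {
  n <- length(x)
  stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
}

# Legendre polynomials P0..P_order evaluated on n equally spaced points over
# [-1, 1] (AFNI polort drift convention).
legendre_basis <- function(n, order) {
  stopifnot(n >= 2, order >= 0, order <= 3)
  x <- seq(-1, 1, length.out = n)
  P <- cbind(rep(1, n), x, (3 * x^2 - 1) / 2, (5 * x^3 - 3 * x) / 2)
  P[, seq_len(order + 1), drop = FALSE]
}
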