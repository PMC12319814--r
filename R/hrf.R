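#' Hemodynamic response function specification
#'
#' Two kernel families are supported: a Gaussian HRF (peak delay and FWHM in
#' seconds) used for the amplitude-modulated regression, and the canonical
#' double-gamma HRF (SPM-style: response gamma peaking near 5 s minus an
#' undershoot gamma scaled by `undershoot_ratio`) used for single-trial
#' designs.
#'
#' @param kind "gaussian" or "double_gamma".
#' @param peak_delay_s Peak delay in seconds (Gaussian kernel).
#' @param width_s FWHM in seconds (Gaussian kernel).
#' @param support_s Kernel support in seconds; the kernel is truncated here.
#' @param undershoot_ratio Ratio of undershoot to response amplitude
#'   (double-gamma kernel).
#' @return An object of class `hrf_spec`.
#' @examples
#' hrf_spec("gaussian")
#' hrf_spec("double_gamma")
#' @export
hrf_spec <- function(kind = c("gaussian", "double_gamma"),
                     peak_delay_s = 5, width_s = 5,
                     support_s = if (kind == "gaussian") 16 else 32,
                     undershoot_ratio = 1 / 6) {
  kind <- match.arg(kind)
  stopifnot(peak_delay_s > 0, width_s > 0, support_s > 0,
            undershoot_ratio >= 0)
  structure(list(kind = kind, peak_delay_s = peak_delay_s,
                 width_s = width_s, support_s = support_s,
                 undershoot_ratio = undershoot_ratio),
            class = "hrf_spec")
}

#' Sample an HRF kernel on a regular grid
#'
#' @param hrf An [hrf_spec()].
#' @param dt_s Sampling interval in seconds.
#' @return Numeric vector of kernel values at `0, dt_s, 2*dt_s, ...` up to
#'   the kernel support, scaled to peak 1.
#' @export
hrf_kernel <- function(hrf, dt_s) {
  stopifnot(inherits(hrf, "hrf_spec"), dt_s > 0)
  t <- seq(0, hrf$support_s, by = dt_s)
  if (hrf$kind == "gaussian") {
    sigma <- hrf$width_s / sqrt(8 * log(2))
    k <- exp(-(t - hrf$peak_delay_s)^2 / (2 * sigma^2))
  } else {
    # canonical double gamma: shapes 6 and 16, rate 1
    k <- stats::dgamma(t, 6, 1) - hrf$undershoot_ratio * stats::dgamma(t, 16, 1)
  }
  k / max(abs(k))
}
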