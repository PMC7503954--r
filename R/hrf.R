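#' Canonical hemodynamic response function
#'
#' Double-gamma impulse response: a positive lobe peaking at
#' \code{peak_time} followed by an undershoot peaking at
#' \code{undershoot_time} with relative amplitude \code{undershoot_ratio},
#' sampled over \code{duration} seconds and normalized to a maximum of 1.
#' The neural square wave of a task design convolved with this kernel gives
#' the expected hemoglobin response used both by the synthetic generator
#' and the GLM regressor.
#'
#' @param sampling_rate Hz.
#' @param peak_time Mode of the positive lobe, s (default 6).
#' @param undershoot_time Mode of the undershoot, s (default 16).
#' @param undershoot_ratio Undershoot amplitude relative to the main lobe
#'   (default 1/6).
#' @param duration Kernel length, s (default 32).
#' @return Numeric vector of kernel samples (first sample at t = 0).
#' @examples
#' h <- canonical_hrf(10)
#' which.max(h) / 10   # close to the 6 s peak
#' @export
canonical_hrf <- function(sampling_rate, peak_time = 6, undershoot_time = 16,
                          undershoot_ratio = 1 / 6, duration = 32) {
  if (sampling_rate <= 0 || peak_time <= 0 || undershoot_time <= 0 ||
      undershoot_ratio < 0 || duration <= 0) {
    stopf("HRF parameters must be positive")
  }
  tt <- seq(0, duration, by = 1 / sampling_rate)
  # gamma densities with unit rate have mode (shape - 1)
  h <- stats::dgamma(tt, shape = peak_time + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(tt, shape = undershoot_time + 1, rate = 1)
  h / max(h)
}

# Convolve a design indicator with the canonical HRF (causal, same length),
# normalized so a sustained block reaches the plateau of the kernel's
# step response scaled to `peak`.
hrf_response <- function(indicator, sampling_rate, peak = 1,
                         hrf_params = list()) {
  kernel <- do.call(canonical_hrf,
                    c(list(sampling_rate = sampling_rate), hrf_params))
  n <- length(indicator)
  y <- stats::convolve(c(indicator, numeric(length(kernel))),
                       rev(kernel), type = "open")
  y <- y[seq_len(n)]
  m <- max(abs(y))
  if (m > 0) y <- y / m * peak
  y
}
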