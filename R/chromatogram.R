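#' Simulate a detector trace
#'
#' Sum of Gaussian peaks (position `tR`, sigma = base width / 4, height from
#' area) on a white-noise baseline, sampled on a regular time grid.
#'
#' @param outcome A `"chrom_outcome"` from [simulate_retention()], or `NULL`
#'   for a peak-free baseline.
#' @param baseline_sigma Baseline noise SD (signal units).
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Trace length in minutes; defaults to the last peak plus
#'   two minutes (or 10 min for a peak-free trace).
#' @param seed Seed for the baseline noise.
#' @return Data frame of class `"chrom_trace"` with columns `time_min`,
#'   `signal`.
#' @export
simulate_chromatogram <- function(outcome = NULL, baseline_sigma = 0.25,
                                  sampling_rate = 5, duration = NULL,
                                  seed = NULL) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration))
    duration <- if (is.null(outcome)) 10
                else max(outcome$tr) + 2
  tt <- seq(0, duration, by = 1 / (sampling_rate * 60))
  sig <- numeric(length(tt))
  if (!is.null(outcome) && nrow(outcome)) {
    for (i in seq_len(nrow(outcome))) {
      s <- outcome$width[i] / 4
      sig <- sig + outcome$height[i] * exp(-(tt - outcome$tr[i])^2 / (2 * s^2))
    }
  }
  if (baseline_sigma > 0)
    sig <- sig + stats::rnorm(length(tt), 0, baseline_sigma)
  structure(data.frame(time_min = tt, signal = sig),
            class = c("chrom_trace", "data.frame"))
}

#' Measure the signal-to-noise ratio of a peak
#'
#' European-Pharmacopoeia-style convention: `S/N = 2 H / h` with `H` the peak
#' height above the local baseline (estimated as the median of the noise
#' window) and `h` the peak-to-peak noise amplitude in a peak-free window.
#'
#' @param trace A `"chrom_trace"`.
#' @param peak_window Numeric `c(start, end)` in minutes containing the peak.
#' @param noise_window Numeric `c(start, end)` in minutes free of peaks.
#' @return Signal-to-noise ratio (single number).
#' @export
measure_snr <- function(trace, peak_window, noise_window) {
  tw <- trace$time_min
  inp <- tw >= peak_window[1] & tw <= peak_window[2]
  inn <- tw >= noise_window[1] & tw <= noise_window[2]
  if (!any(inp) || !any(inn)) stop("window outside the trace span")
  noise <- trace$signal[inn]
  h <- max(noise) - min(noise)
  if (h <= 0) stop("degenerate noise window: zero peak-to-peak amplitude")
  H <- max(trace$signal[inp]) - stats::median(noise)
  2 * H / h
}
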