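#' Phase-amplitude coupling modulation index
#'
#' Normalized-entropy (Tort-style) index: band-pass both signals, take the
#' instantaneous phase of the phase band and amplitude envelope of the
#' amplitude band via the analytic signal, average the amplitude within
#' \code{n_bins} phase bins, normalize to a distribution P, and return
#' \code{MI = (log N - H(P)) / log N}. MI is 0 for phase-independent
#' amplitude and 1 when all amplitude concentrates in one bin.
#'
#' @param phase_signal,amp_signal equal-length numeric signals (may be the
#'   same channel).
#' @param rate sampling rate, Hz.
#' @param phase_band \code{c(low, high)} Hz for the phase-providing band.
#' @param amp_band \code{c(low, high)} Hz for the amplitude-providing band.
#' @param n_bins number of phase bins (default 18, i.e. 20-degree bins).
#' @return MI scalar in [0, 1].
#' @export
modulation_index <- function(phase_signal, amp_signal, rate, phase_band,
                             amp_band, n_bins = 18) {
  assert_that(length(phase_signal) == length(amp_signal),
              "signals must have equal length")
  assert_that(n_bins >= 2, "need at least 2 phase bins")
  ph <- fir_bandpass(phase_signal, rate, phase_band[1], phase_band[2])
  am <- fir_bandpass(amp_signal, rate, amp_band[1], amp_band[2])
  phase <- Arg(analytic_signal(ph))
  amp <- Mod(analytic_signal(am))
  # trim filter edges: half the longer filter at each end
  n_taps <- max(fir_bandpass_ntaps(rate, phase_band[1], n_signal = length(ph)),
                fir_bandpass_ntaps(rate, amp_band[1], n_signal = length(am)))
  trim <- ceiling(n_taps / 2)
  keep <- (trim + 1):(length(phase) - trim)
  assert_that(length(keep) > n_bins * 10, "signal too short after edge trimming",
              "too_short_error")
  mi_from_phase_amp(phase[keep], amp[keep], n_bins)
}

# core binned-entropy computation on instantaneous phase/amplitude series
mi_from_phase_amp <- function(phase, amp, n_bins) {
  if (all(amp == 0))
    stop_ictalysis("degenerate input: all-zero amplitude envelope",
                   "degenerate_input_error")
  bins <- floor((phase + pi) / (2 * pi) * n_bins) + 1L
  bins[bins > n_bins] <- n_bins  # phase == pi lands in the last bin
  mean_amp <- vapply(seq_len(n_bins), function(j) {
    v <- amp[bins == j]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  p <- mean_amp / sum(mean_amp)
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  (log(n_bins) - h) / log(n_bins)
}

#' Phase-amplitude comodulogram
#'
#' Grid of \code{\link{modulation_index}} values over a single phase band
#' range scanned in steps against amplitude bands of fixed bandwidth
#' (default 4 Hz at 2-Hz steps from 2 to 200 Hz). Phase and amplitude
#' sources may be different channels (e.g. prefrontal 4-Hz phase against
#' hippocampal gamma amplitude).
#'
#' @param phase_source,amp_source equal-length numeric signals.
#' @param rate sampling rate, Hz.
#' @param phase_range \code{c(low, high)} Hz scanned for the phase band
#'   (default 4-8).
#' @param phase_bw,phase_step phase band bandwidth and step, Hz (defaults 2
#'   and 2).
#' @param amp_range amplitude frequency range, Hz (default 2-200; truncated
#'   at Nyquist with a warning).
#' @param amp_bw,amp_step amplitude bandwidth and step, Hz (defaults 4, 2).
#' @param n_bins phase bins (default 18).
#' @return object of class \code{comodulogram}: \code{phase_freqs},
#'   \code{amp_freqs} (band centers), \code{mi} (phase x amplitude matrix).
#' @export
comodulogram <- function(phase_source, amp_source, rate,
                         phase_range = c(4, 8), phase_bw = 2, phase_step = 2,
                         amp_range = c(2, 200), amp_bw = 4, amp_step = 2,
                         n_bins = 18) {
  nyq <- rate / 2
  if (amp_range[2] + amp_bw / 2 > nyq) {
    warning("amplitude range truncated at Nyquist")
    amp_range[2] <- nyq - amp_bw / 2 - 1e-9
  }
  assert_that(amp_range[2] > amp_range[1], "amplitude range collapsed", "validation_error")
  phase_centers <- seq(phase_range[1] + phase_bw / 2,
                       phase_range[2] - phase_bw / 2 + 1e-9, by = phase_step)
  amp_centers <- seq(amp_range[1] + amp_bw / 2, amp_range[2], by = amp_step)
  mi <- matrix(NA_real_, length(phase_centers), length(amp_centers))
  for (i in seq_along(phase_centers)) {
    pb <- c(phase_centers[i] - phase_bw / 2, phase_centers[i] + phase_bw / 2)
    for (j in seq_along(amp_centers)) {
      ab <- c(max(amp_centers[j] - amp_bw / 2, 0.5),
              min(amp_centers[j] + amp_bw / 2, nyq * 0.999))
      mi[i, j] <- modulation_index(phase_source, amp_source, rate, pb, ab,
                                   n_bins)
    }
  }
  structure(list(phase_freqs = phase_centers, amp_freqs = amp_centers,
                 mi = mi, n_bins = n_bins),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  peak <- which(x$mi == max(x$mi), arr.ind = TRUE)[1, ]
  cat(sprintf("<comodulogram> %d x %d cells; max MI %.4f at (%g Hz phase, %g Hz amp)\n",
              nrow(x$mi), ncol(x$mi), max(x$mi),
              x$phase_freqs[peak[1]], x$amp_freqs[peak[2]]))
  invisible(x)
}

#' Surrogate threshold for a modulation index
#'
#' Circularly time-shifts the amplitude signal relative to the phase signal
#' and recomputes MI, returning the requested surrogate quantile. Values of
#' the observed MI below this threshold are consistent with no coupling.
#'
#' @inheritParams modulation_index
#' @param n_surrogates number of circular shifts (default 20).
#' @param probs quantile to report (default 0.95).
#' @param seed RNG seed.
#' @return the surrogate MI quantile.
#' @export
mi_surrogate_threshold <- function(phase_signal, amp_signal, rate, phase_band,
                                   amp_band, n_bins = 18, n_surrogates = 20,
                                   probs = 0.95, seed = 1) {
  n <- length(amp_signal)
  with_seed(seed, {
    mis <- vapply(seq_len(n_surrogates), function(s) {
      k <- sample.int(n - 2L, 1L) + 1L
      shifted <- c(amp_signal[k:n], amp_signal[1:(k - 1L)])
      modulation_index(phase_signal, shifted, rate, phase_band, amp_band,
                       n_bins)
    }, numeric(1))
    stats::quantile(mis, probs, names = FALSE)
  })
}
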