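#' Preprocess an LFP channel for spectral analysis
#'
#' Downsamples to the target rate (integer factor, FIR anti-alias) and
#' band-pass filters 0.1-100 Hz, the conditioning applied before power and
#' coherence estimation.
#'
#' @param x numeric signal.
#' @param rate sampling rate of \code{x} in Hz.
#' @param cfg an \code{\link{analysis_config}} (fields \code{target_rate},
#'   \code{bp_low}, \code{bp_high}).
#' @return list with \code{x} (filtered signal) and \code{rate}.
#' @export
preprocess_lfp <- function(x, rate, cfg = analysis_config()) {
  assert_that(rate >= cfg$target_rate, "sampling rate below target rate")
  if (rate > cfg$target_rate) {
    q <- rate / cfg$target_rate
    assert_that(abs(q - round(q)) < 1e-9,
                "rate must be an integer multiple of target_rate")
    x <- as.numeric(signal::decimate(x, round(q), ftype = "fir"))
    rate <- cfg$target_rate
  }
  lp <- signal::butter(4, cfg$bp_high / (rate / 2), type = "low")
  x <- as.numeric(signal::filtfilt(lp, x))
  # slow drift removed by subtracting a long moving average: a 0.1-Hz IIR
  # high-pass at this rate is numerically fragile in transfer-function form
  w <- round(rate / cfg$bp_low)
  if (w < length(x)) x <- x - moving_average(x, w)
  list(x = x, rate = rate)
}

segment_starts <- function(n, seg_len, overlap_len) {
  step <- seg_len - overlap_len
  assert_that(step >= 1, "overlap must be shorter than the segment")
  seq(1L, n - seg_len + 1L, by = step)
}

mt_spectra <- function(x, y = NULL, rate, segment_ms, overlap_ms, tw, k) {
  n <- length(x)
  seg_len <- round(segment_ms / 1000 * rate)
  overlap_len <- round(overlap_ms / 1000 * rate)
  assert_that(n >= seg_len, "signal shorter than one segment", "too_short_error")
  tapers <- dpss_tapers(seg_len, tw, k)
  starts <- segment_starts(n, seg_len, overlap_len)
  n_half <- floor(seg_len / 2) + 1L
  sxx <- numeric(n_half); syy <- numeric(n_half)
  sxy <- complex(real = numeric(n_half), imaginary = numeric(n_half))
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1L)]
    xs <- xs - mean(xs)
    fx <- stats::mvfft(tapers * xs)[seq_len(n_half), , drop = FALSE]
    sxx <- sxx + rowMeans(Mod(fx)^2)
    if (!is.null(y)) {
      ys <- y[s:(s + seg_len - 1L)]
      ys <- ys - mean(ys)
      fy <- stats::mvfft(tapers * ys)[seq_len(n_half), , drop = FALSE]
      syy <- syy + rowMeans(Mod(fy)^2)
      sxy <- sxy + rowMeans(fx * Conj(fy))
    }
  }
  n_seg <- length(starts)
  freqs <- (seq_len(n_half) - 1L) * rate / seg_len
  list(freqs = freqs, sxx = sxx / n_seg, syy = syy / n_seg, sxy = sxy / n_seg,
       n_segments = n_seg, seg_len = seg_len)
}

#' Multitaper power spectral density
#'
#' Welch-style segmentation with DPSS tapers: per-segment, per-taper
#' periodograms are averaged (uniform taper weights) and normalized as a
#' one-sided density so that \code{sum(power) * df} recovers the signal
#' variance (within taper bias).
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param segment_ms segment length in ms (default 5000).
#' @param overlap_ms overlap length in ms (default 500).
#' @param tw time-bandwidth product (default 3).
#' @param n_tapers number of DPSS tapers (default 5; at most \code{2 tw - 1}).
#' @return object of class \code{spectral_density}: \code{freqs}, \code{power},
#'   \code{params}.
#' @export
multitaper_psd <- function(x, rate, segment_ms = 5000, overlap_ms = 500,
                           tw = 3, n_tapers = 5) {
  assert_that(n_tapers <= 2 * tw - 1, "n_tapers must be <= 2*TW - 1")
  sp <- mt_spectra(x, NULL, rate, segment_ms, overlap_ms, tw, n_tapers)
  pow <- sp$sxx / rate
  one_sided <- rep(2, length(pow))
  one_sided[1L] <- 1
  if (sp$seg_len %% 2 == 0) one_sided[length(pow)] <- 1
  structure(list(freqs = sp$freqs, power = pow * one_sided,
                 n_segments = sp$n_segments,
                 params = list(segment_ms = segment_ms, overlap_ms = overlap_ms,
                               tw = tw, n_tapers = n_tapers)),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("<spectral_density> %d frequencies (0-%.1f Hz), %d segments, TW=%g K=%d\n",
              length(x$freqs), max(x$freqs), x$n_segments,
              x$params$tw, x$params$n_tapers))
  invisible(x)
}

#' Multitaper magnitude-squared coherence
#'
#' Cross- and auto-spectra are averaged over tapers and segments before
#' forming \code{|Sxy|^2 / (Sxx Syy)}, so the estimate lies in [0, 1] and
#' its bias under independence shrinks as 1/(segments x tapers).
#'
#' @param x,y equal-length numeric signals.
#' @param rate sampling rate, Hz.
#' @param segment_ms segment length in ms (default 2000).
#' @param overlap_ms overlap length in ms (default 100).
#' @param tw time-bandwidth product (default 5).
#' @param n_tapers number of tapers (default 9).
#' @return object of class \code{coherence_spectrum}: \code{freqs},
#'   \code{coherence}, \code{n_segments}, \code{params}.
#' @export
multitaper_coherence <- function(x, y, rate, segment_ms = 2000,
                                 overlap_ms = 100, tw = 5, n_tapers = 9) {
  assert_that(length(x) == length(y), "signals must have equal length")
  assert_that(n_tapers <= 2 * tw - 1, "n_tapers must be <= 2*TW - 1")
  sp <- mt_spectra(x, y, rate, segment_ms, overlap_ms, tw, n_tapers)
  assert_that(sp$n_segments >= 2,
              "coherence needs at least 2 segments (degenerate at 1)",
              "too_short_error")
  coh <- Mod(sp$sxy)^2 / (sp$sxx * sp$syy)
  coh[!is.finite(coh)] <- 0
  structure(list(freqs = sp$freqs, coherence = pmin(pmax(coh, 0), 1),
                 n_segments = sp$n_segments,
                 params = list(segment_ms = segment_ms, overlap_ms = overlap_ms,
                               tw = tw, n_tapers = n_tapers)),
            class = "coherence_spectrum")
}

#' Band averages of a spectrum
#'
#' Arithmetic mean of spectral values over grid points falling in each
#' half-open band \code{[low, high)}.
#'
#' @param spectrum a \code{spectral_density}, \code{coherence_spectrum}, or
#'   any list with \code{freqs} and a value vector.
#' @param bands named list of \code{c(low, high)} pairs in Hz; defaults to
#'   theta 6-10, slow-gamma 20-40, fast-gamma 60-80.
#' @return named numeric vector of band means.
#' @export
band_average <- function(spectrum,
                         bands = analysis_config()$bands) {
  vals <- if (!is.null(spectrum$power)) spectrum$power
          else if (!is.null(spectrum$coherence)) spectrum$coherence
          else stop_ictalysis("spectrum has no power or coherence field",
                              "validation_error")
  freqs <- spectrum$freqs
  out <- vapply(bands, function(b) {
    sel <- in_half_open(freqs, b[1], b[2])
    assert_that(any(sel), sprintf("band [%g, %g) contains no grid points",
                                  b[1], b[2]), "empty_band_error")
    mean(vals[sel])
  }, numeric(1))
  out
}

#' Morlet wavelet spectrogram
#'
#' Convolution with complex Morlet wavelets of constant cycle count;
#' power is the squared magnitude. Samples within half the wavelet support
#' of either edge are set to NA.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param freqs frequencies of interest, Hz (all below Nyquist).
#' @param cycles wavelet width in cycles (default 7, constant across
#'   frequency).
#' @return list: \code{times} (s), \code{freqs} (Hz), \code{power}
#'   (frequency x time, NA at invalid edges).
#' @export
morlet_spectrogram <- function(x, rate, freqs, cycles = 7) {
  assert_that(all(freqs > 0 & freqs < rate / 2),
              "frequencies must lie in (0, Nyquist)")
  n <- length(x)
  pow <- matrix(NA_real_, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sd_t <- cycles / (2 * pi * f)
    half <- ceiling(3.5 * sd_t * rate)
    t <- (-half:half) / rate
    w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sd_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    m <- length(w)
    nfft <- stats::nextn(n + m - 1L)
    conv <- stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(w, complex(real = numeric(nfft - m)))),
                       inverse = TRUE) / nfft
    centered <- conv[(half + 1L):(half + n)]
    p <- Mod(centered)^2
    if (half >= 1) p[c(seq_len(min(half, n)),
                       seq.int(max(n - half + 1L, 1L), n))] <- NA_real_
    pow[i, ] <- p
  }
  list(times = (seq_len(n) - 1L) / rate, freqs = freqs, power = pow)
}
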