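#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft convolve sd var lm coef cor cor.test pnorm quantile
#'   rnorm runif rpois rexp rbinom approx spline qr qr.Q setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

stop_ictalysis <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ictalysis_error")))
}

assert_that <- function(ok, msg, class = "validation_error") {
  if (!isTRUE(ok)) stop_ictalysis(msg, class)
  invisible(TRUE)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal \code{x + i H(x)} whose argument is
#' the instantaneous phase and whose modulus is the instantaneous amplitude
#' envelope of \code{x}.
#'
#' @param x numeric vector, a real-valued signal.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  assert_that(is.numeric(x) && length(x) > 1L, "signal must be numeric, length > 1")
  assert_that(all(is.finite(x)), "signal must be finite")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# centered moving average, edges shrink to available samples
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# zero-phase FIR band-pass; transition bands sized relative to band edges so
# that phase estimates stay lag-free (filtfilt doubles the attenuation)
fir_bandpass <- function(x, rate, low, high, trans_frac = 0.2) {
  assert_that(low > 0 && high > low, "band must satisfy 0 < low < high")
  assert_that(high < rate / 2, "band must lie below Nyquist")
  width <- max(low * trans_frac, 1.0)
  n_taps <- max(3 * round(rate / width), 15)
  n_taps <- min(n_taps, floor(length(x) / 3) * 2 - 1)
  if (n_taps %% 2 == 0) n_taps <- n_taps - 1L
  assert_that(n_taps >= 15, "signal too short for band-pass filter", "too_short_error")
  fir <- signal::fir1(n_taps - 1, c(low, high) / (rate / 2), type = "pass")
  fir_apply_centered(x, as.numeric(fir))
}

# apply a symmetric (linear-phase) FIR by centered FFT convolution; the
# symmetric kernel makes a single pass zero-phase
fir_apply_centered <- function(x, fir) {
  n <- length(x); m <- length(fir)
  half <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L)
  conv <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                        stats::fft(c(fir, numeric(nfft - m))),
                        inverse = TRUE)) / nfft
  conv[(half + 1L):(half + n)]
}

# number of taps used by fir_bandpass for a given design (edge-trim helper)
fir_bandpass_ntaps <- function(rate, low, trans_frac = 0.2, n_signal = Inf) {
  width <- max(low * trans_frac, 1.0)
  n_taps <- max(3 * round(rate / width), 15)
  n_taps <- min(n_taps, floor(n_signal / 3) * 2 - 1)
  if (n_taps %% 2 == 0) n_taps <- n_taps - 1L
  n_taps
}

tukey_window <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
                "seed must be a single finite number")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# half-open interval membership [lo, hi)
in_half_open <- function(x, lo, hi) x >= lo & x < hi
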