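#' Synthesis specification for a simulated recording session
#'
#' Declares the statistical structure of a synthetic LFP session: 1/f
#' background, band-limited oscillators (hippocampal theta, prefrontal 4-Hz,
#' gamma), theta-phase-modulated gamma amplitude, Poisson interictal
#' discharges with calibrated z-amplitude, contralateral propagation with
#' lag and jitter, and the session seed. Defaults match the control-group
#' regime of the emulated study: discharge rate 0.41 Hz, target z-amplitude
#' 29.6, waveform support 0.44 s, contralateral lag 30 ms.
#'
#' @param duration session length, s.
#' @param sample_rate sampling rate, Hz.
#' @param background list: \code{exponent} (1/f slope) and \code{rms} (uV).
#' @param oscillators list of lists with \code{freq}, \code{bw}, \code{rms},
#'   \code{channels} (character vector of channel names).
#' @param pac list: \code{phase_freq}, \code{amp_freq}, \code{depth} in
#'   [0,1], \code{channels}.
#' @param discharges list: \code{rate} (Hz), \code{amplitude} (target
#'   z-score), \code{duration} (s, waveform support), \code{carrier}
#'   (Hz), \code{damping} (decay constant as multiple of support).
#' @param propagation list: \code{lag_mean}, \code{lag_jitter} (s),
#'   \code{probability}.
#' @param spikes list: \code{baseline} (Hz), \code{gain}, \code{kernel} (s).
#' @param speed list: \code{baseline} (cm/s), \code{dip} in [0,1],
#'   \code{recovery} (s), \code{noise_cv}.
#' @param seed integer fixing all randomness.
#' @return object of class \code{synthesis_spec}.
#' @export
synthesis_spec <- function(duration = 600, sample_rate = 1000,
                           background = list(exponent = 1, rms = 1),
                           oscillators = list(
                             list(freq = 7, bw = 2, rms = 0.5,
                                  channels = c("CA1_R", "CA1_L")),
                             list(freq = 4, bw = 1, rms = 0.5,
                                  channels = "PFC"),
                             list(freq = 80, bw = 20, rms = 0.1,
                                  channels = c("CA1_R", "CA1_L"))),
                           pac = list(phase_freq = 7, amp_freq = 80,
                                      depth = 0.6,
                                      channels = c("CA1_R", "CA1_L")),
                           discharges = list(rate = 0.41, amplitude = 29.6,
                                             duration = 0.44, carrier = 120,
                                             damping = 4),
                           propagation = list(lag_mean = 0.03,
                                              lag_jitter = 0.005,
                                              probability = 0.9),
                           spikes = list(baseline = 6.7, gain = 2,
                                         kernel = 0.2),
                           speed = list(baseline = 8, dip = 0.5,
                                        recovery = 1, noise_cv = 0.1),
                           seed = 1) {
  assert_that(duration > 0 && sample_rate > 0, "duration and rate must be positive")
  assert_that(discharges$rate >= 0, "discharge rate must be >= 0")
  assert_that(pac$depth >= 0 && pac$depth <= 1, "PAC depth must be in [0,1]")
  assert_that(propagation$probability >= 0 && propagation$probability <= 1,
              "propagation probability must be in [0,1]")
  assert_that(speed$dip >= 0 && speed$dip <= 1, "speed dip must be in [0,1]")
  structure(list(duration = duration, sample_rate = sample_rate,
                 background = background, oscillators = oscillators,
                 pac = pac, discharges = discharges,
                 propagation = propagation, spikes = spikes, speed = speed,
                 seed = seed),
            class = "synthesis_spec")
}

# 1/f^exponent background by spectral shaping of white noise
gen_background <- function(n, rate, exponent, rms) {
  wn <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1)) * rate / n
  f[(floor(n / 2) + 2):n] <- f[rev(2:ceiling(n / 2))]
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(stats::fft(stats::fft(wn) * shape, inverse = TRUE) / n)
  x * rms / stats::sd(x)
}

# band-limited oscillator: narrowband-filtered white noise at target RMS
gen_oscillator <- function(n, rate, freq, bw, rms) {
  x <- fir_bandpass(stats::rnorm(n), rate, max(freq - bw / 2, 0.5),
                    min(freq + bw / 2, rate / 2 * 0.95))
  x * rms / stats::sd(x)
}

#' Stereotyped discharge waveform
#'
#' A damped fast (default 80 Hz) cosine under a flat-topped Tukey envelope
#' spanning \code{duration} seconds, with a slow negative sag. The fast
#' carrier puts the event's energy above the 40-Hz detection cutoff; the
#' flat-topped envelope makes the detected 2-SD extent track the stated
#' support.
#'
#' @param duration waveform support, s.
#' @param rate sampling rate, Hz.
#' @param carrier carrier frequency, Hz (default 120, above the gamma band
#'   so the event does not beat against the gamma oscillator).
#' @param damping exponential decay constant as a multiple of the support
#'   (default 4).
#' @param alpha Tukey taper fraction of the support (default 0.12).
#' @return numeric vector of length \code{round(duration * rate)}, peak
#'   absolute value 1.
#' @export
discharge_waveform <- function(duration, rate, carrier = 120, damping = 4,
                               alpha = 0.12) {
  nw <- round(duration * rate)
  assert_that(nw >= 8, "waveform support too short for the sampling rate",
              "too_short_error")
  t <- (seq_len(nw) - 1) / rate
  env <- tukey_window(nw, alpha = alpha) * exp(-t / (damping * duration))
  w <- env * cos(2 * pi * carrier * t) - 0.3 * sin(pi * t / duration)
  w / max(abs(w))
}

add_waveform_at <- function(x, w, idx) {
  n <- length(x); m <- length(w)
  j <- idx:(idx + m - 1L)
  ok <- j >= 1L & j <= n
  x[j[ok]] <- x[j[ok]] + w[ok]
  x
}

#' Generate a synthetic LFP session with ground truth
#'
#' Builds channels CA1_R, CA1_L and PFC: 1/f background plus band-limited
#' oscillators; on PAC-flagged channels the gamma component's amplitude
#' follows \code{1 + depth * cos(theta phase)}; interictal discharges are
#' injected on CA1_R as a Poisson process and copied to CA1_L at a lagged,
#' jittered delay with the stated probability. The injected waveform is
#' scaled by an iterative inject-measure-rescale loop so that the detection
#' statistic's z-amplitude at the event peaks (with an event-excluded
#' baseline) matches the target.
#'
#' @param spec a \code{\link{synthesis_spec}}.
#' @return list with \code{recording} (a
#'   \code{\link{continuous_recording}}) and \code{truth} (injected times
#'   per channel, lags, PAC depth, calibrated scale).
#' @export
gen_lfp <- function(spec) {
  assert_that(inherits(spec, "synthesis_spec"), "spec must be a synthesis_spec")
  rate <- spec$sample_rate
  n <- round(spec$duration * rate)
  if (spec$discharges$rate > 0)
    assert_that(spec$duration >= 2 * spec$discharges$duration,
                "duration too short to hold one discharge waveform",
                "too_short_error")
  with_seed(spec$seed, {
    chans <- c("CA1_R", "CA1_L", "PFC")
    base <- lapply(chans, function(ch)
      gen_background(n, rate, spec$background$exponent, spec$background$rms))
    names(base) <- chans
    # theta component shared within hippocampus so PAC phase is well defined
    theta_osc <- spec$oscillators[[1]]
    theta <- gen_oscillator(n, rate, theta_osc$freq, theta_osc$bw, theta_osc$rms)
    theta_phase <- Arg(analytic_signal(theta))
    for (osc in spec$oscillators) {
      is_theta <- identical(osc$freq, theta_osc$freq) &&
        identical(osc$channels, theta_osc$channels)
      for (ch in osc$channels) {
        if (is_theta) { base[[ch]] <- base[[ch]] + theta; next }
        comp <- gen_oscillator(n, rate, osc$freq, osc$bw, osc$rms)
        if (!is.null(spec$pac) && spec$pac$depth > 0 &&
            ch %in% spec$pac$channels &&
            abs(osc$freq - spec$pac$amp_freq) < osc$bw) {
          mod <- 1 + spec$pac$depth * cos(theta_phase)
          comp <- comp * mod / sqrt(mean(mod^2))
        }
        base[[ch]] <- base[[ch]] + comp
      }
    }
    # discharge injection with amplitude calibration
    truth <- list(discharge_times = list(CA1_R = numeric(0), CA1_L = numeric(0)),
                  lags = numeric(0), pac_depth = spec$pac$depth,
                  discharge_scale = NA_real_)
    if (spec$discharges$rate > 0) {
      dd <- spec$discharges
      w <- discharge_waveform(dd$duration, rate, dd$carrier, dd$damping)
      nw <- length(w)
      margin <- dd$duration
      # Poisson-like process with a refractory dead time (2.5x support) so
      # successive discharges do not fuse; gap distribution is dead time +
      # exponential with the rate adjusted to preserve the nominal density
      dead <- 2.5 * dd$duration
      assert_that(1 / dd$rate > dead,
                  "discharge rate too high for the waveform support")
      lam <- 1 / (1 / dd$rate - dead)
      n_draw <- ceiling(spec$duration * dd$rate * 2 + 20)
      t_r <- cumsum(dead + stats::rexp(n_draw, lam))
      t_r <- t_r[t_r < spec$duration - margin & t_r > margin]
      prop <- stats::runif(length(t_r)) < spec$propagation$probability
      lags <- spec$propagation$lag_mean +
        stats::rnorm(length(t_r), 0, spec$propagation$lag_jitter)
      t_l <- (t_r + pmax(lags, 0))[prop]
      idx_r <- round(t_r * rate) + 1L
      idx_l <- round(t_l * rate) + 1L
      # event mask for the calibration baseline
      mask <- rep(TRUE, n)
      for (i in idx_r) mask[max(1, i - 50):min(n, i + nw + 50)] <- FALSE
      scale <- calibrate_scale(base$CA1_R, w, idx_r, mask, rate,
                               dd$amplitude)
      for (i in idx_r) base$CA1_R <- add_waveform_at(base$CA1_R, scale * w, i)
      for (i in idx_l) base$CA1_L <- add_waveform_at(base$CA1_L, scale * w, i)
      truth$discharge_times <- list(CA1_R = t_r, CA1_L = t_l)
      truth$lags <- lags[prop]
      truth$discharge_scale <- scale
    }
    info <- data.frame(name = chans,
                       region = c("CA1", "CA1", "PFC"),
                       hemisphere = c("R", "L", "R"),
                       stringsAsFactors = FALSE)
    rec <- continuous_recording(do.call(rbind, base), rate, info)
    list(recording = rec, truth = truth)
  })
}

# iterative inject -> measure -> rescale loop: the z-amplitude depends on
# the recording's own variance, so the scale cannot be set in closed form
calibrate_scale <- function(bg, w, idx, mask, rate, target,
                            tol = 0.02, max_iter = 6) {
  if (length(idx) == 0L) return(1)
  bf <- signal::butter(4, 40 / (rate / 2), type = "high")
  hp_bg_sd <- stats::sd(as.numeric(signal::filtfilt(bf, bg))[mask])
  scale <- sqrt(target * sqrt(2)) * hp_bg_sd  # Gaussian-baseline first guess
  nw <- length(w)
  for (k in seq_len(max_iter)) {
    x <- bg
    for (i in idx) x <- add_waveform_at(x, scale * w, i)
    z <- detection_statistic(x, rate, baseline_mask = mask)
    peaks <- vapply(idx, function(i)
      max(z[i:min(length(z), i + nw - 1L)]), numeric(1))
    measured <- mean(peaks)
    if (measured <= 0) { scale <- scale * 2; next }
    if (abs(measured - target) / target < tol) break
    scale <- scale * sqrt(target / measured)
  }
  scale
}

#' Generate a spike train modulated by discharge onsets
#'
#' Inhomogeneous Poisson process with rate
#' \code{baseline * (1 + gain * k(t))} where \code{k} is a causal
#' exponential kernel (unit peak) following each discharge onset.
#'
#' @param discharges an \code{\link{event_train}} of discharge onsets.
#' @param baseline baseline firing rate, Hz (> 0).
#' @param gain multiplicative rate gain at the kernel peak (> -1).
#' @param kernel_width exponential decay constant, s.
#' @param duration train duration, s.
#' @param seed RNG seed.
#' @return an \code{event_train} labelled "spike".
#' @export
gen_spike_train <- function(discharges, baseline, gain, kernel_width,
                            duration, seed = 1) {
  assert_that(baseline > 0, "baseline rate must be positive")
  assert_that(gain > -1, "gain below -1 would make the rate negative")
  if (duration <= 0) return(event_train(numeric(0), "spike", 0))
  with_seed(seed, {
    dt <- 0.001
    tt <- seq(0, duration - dt, by = dt)
    k <- numeric(length(tt))
    for (d in discharges$times) {
      after <- tt >= d
      k[after] <- k[after] + exp(-(tt[after] - d) / kernel_width)
    }
    rate_t <- baseline * (1 + gain * k)
    rate_t[rate_t < 0] <- 0
    counts <- stats::rpois(length(tt), rate_t * dt)
    times <- rep(tt, counts) + stats::runif(sum(counts), 0, dt)
    event_train(sort(times), "spike", duration, warn_unsorted = FALSE)
  })
}

#' Generate a locomotion speed trace with post-discharge dips
#'
#' Positive noisy speed at the stated baseline with a multiplicative
#' \code{(1 - dip)} drop at each discharge onset recovering exponentially.
#'
#' @param discharges an \code{\link{event_train}}.
#' @param baseline mean speed, cm/s (> 0).
#' @param dip fractional drop in [0, 1].
#' @param recovery exponential recovery constant, s.
#' @param fps frame rate (> 0).
#' @param duration trace duration, s (defaults to the train's duration).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @return a \code{speed_trace} (see \code{\link{compute_speed}}).
#' @export
gen_speed_trace <- function(discharges, baseline, dip, recovery, fps = 30,
                            duration = discharges$duration, noise_cv = 0.1,
                            seed = 1) {
  assert_that(fps > 0, "fps must be positive")
  assert_that(baseline > 0, "baseline speed must be positive")
  assert_that(dip >= 0 && dip <= 1, "dip must be in [0, 1]")
  with_seed(seed, {
    tt <- seq(0, duration, by = 1 / fps)
    m <- rep(1, length(tt))
    for (d in discharges$times) {
      after <- tt >= d
      m[after] <- m[after] * (1 - dip * exp(-(tt[after] - d) / recovery))
    }
    sp <- baseline * m * exp(stats::rnorm(length(tt), 0, noise_cv))
    speed_trace(tt, pmax(sp, 0), fps)
  })
}

#' Simulate a probabilistic-reversal operant session
#'
#' Lateral-port pokes rewarded at 80/20 (configurable) with the high port
#' reversing after a block length drawn uniformly from
#' \code{block_mean +/- block_jitter} trials. The simulated agent follows a
#' win-stay/lose-shift policy, an oracle policy (always the current high
#' port), or random choice.
#'
#' @param n_trials number of lateral pokes to simulate (> 0).
#' @param p_high reward probability at the high port (0 < p < 1); the low
#'   port pays \code{1 - p_high}.
#' @param block_mean,block_jitter block length parameters in trials
#'   (\code{block_mean > block_jitter >= 0}).
#' @param policy list: \code{type} in "wsls", "oracle", "random";
#'   for wsls \code{p_stay_win}, \code{p_shift_lose}; \code{p_collect}
#'   probability a rewarded pellet is collected; \code{latency_mean}
#'   exponential mean of poke-to-collection latency, s.
#' @param iti_mean mean inter-trial interval, s.
#' @param seed RNG seed.
#' @return object of class \code{fed_log}: data.frame \code{trials} with
#'   time_s, port, rewarded, block, high_port, collect_time.
#' @export
gen_fed_session <- function(n_trials, p_high = 0.8, block_mean = 15,
                            block_jitter = 2,
                            policy = list(type = "wsls", p_stay_win = 0.8,
                                          p_shift_lose = 0.6,
                                          p_collect = 0.95,
                                          latency_mean = 2),
                            iti_mean = 5, seed = 1) {
  assert_that(n_trials > 0, "n_trials must be positive")
  assert_that(p_high > 0 && p_high < 1, "p_high must be in (0, 1)")
  assert_that(block_mean > block_jitter && block_jitter >= 0,
              "need block_mean > block_jitter >= 0")
  with_seed(seed, {
    p_low <- 1 - p_high
    high <- sample(c("left", "right"), 1)
    block_len <- function() sample(seq(block_mean - block_jitter,
                                       block_mean + block_jitter), 1)
    remaining <- block_len()
    block <- 1L
    port <- character(n_trials); rewarded <- logical(n_trials)
    blocks <- integer(n_trials); highs <- character(n_trials)
    collect <- rep(NA_real_, n_trials)
    times <- cumsum(stats::rexp(n_trials, 1 / iti_mean))
    prev_port <- sample(c("left", "right"), 1)
    prev_win <- FALSE
    p_collect <- if (is.null(policy$p_collect)) 1 else policy$p_collect
    lat_mean <- if (is.null(policy$latency_mean)) 2 else policy$latency_mean
    for (i in seq_len(n_trials)) {
      choice <- switch(policy$type,
        oracle = high,
        random = sample(c("left", "right"), 1),
        wsls = if (i == 1L) prev_port
               else if (prev_win) {
                 if (stats::runif(1) < policy$p_stay_win) prev_port
                 else setdiff(c("left", "right"), prev_port)
               } else {
                 if (stats::runif(1) < policy$p_shift_lose)
                   setdiff(c("left", "right"), prev_port)
                 else prev_port
               },
        stop_ictalysis("unknown policy type", "validation_error"))
      p <- if (choice == high) p_high else p_low
      win <- stats::runif(1) < p
      port[i] <- choice; rewarded[i] <- win
      blocks[i] <- block; highs[i] <- high
      if (win && stats::runif(1) < p_collect)
        collect[i] <- times[i] + stats::rexp(1, 1 / lat_mean)
      prev_port <- choice; prev_win <- win
      remaining <- remaining - 1L
      if (remaining == 0L) {
        high <- setdiff(c("left", "right"), high)
        block <- block + 1L
        remaining <- block_len()
      }
    }
    structure(list(trials = data.frame(
      time_s = times, port = port, rewarded = rewarded, block = blocks,
      high_port = highs, collect_time = collect, stringsAsFactors = FALSE)),
      class = "fed_log")
  })
}

#' @export
print.fed_log <- function(x, ...) {
  cat(sprintf("<fed_log> %d trials, %d blocks, %.1f%% rewarded\n",
              nrow(x$trials), max(x$trials$block),
              100 * mean(x$trials$rewarded)))
  invisible(x)
}

#' Write / read FED logs as CSV
#' @param log a \code{fed_log}.
#' @param path CSV path.
#' @export
write_fed_log <- function(log, path) {
  utils::write.csv(log$trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fed_log
#' @export
read_fed_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("time_s", "port", "rewarded") %in% names(df)),
              "FED CSV needs time_s, port, rewarded columns", "format_error")
  df$rewarded <- as.logical(df$rewarded)
  structure(list(trials = df), class = "fed_log")
}

#' Generate linear multi-day learning curves
#'
#' \code{y_d = intercept + slope * d + Normal(0, noise_sd)} for days
#' \code{1..days}.
#'
#' @param days number of training days (>= 3).
#' @param slope slope in metric units/day.
#' @param intercept intercept in metric units.
#' @param noise_sd noise SD (>= 0).
#' @param seed RNG seed.
#' @return data.frame with \code{day} and \code{value}.
#' @export
gen_training_curves <- function(days, slope, intercept, noise_sd, seed = 1) {
  assert_that(days >= 3, "need at least 3 days")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  with_seed(seed, {
    d <- seq_len(days)
    data.frame(day = d,
               value = intercept + slope * d + stats::rnorm(days, 0, noise_sd))
  })
}
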