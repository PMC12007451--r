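# shared fixtures built in code

# small quiet recording: white-noise background only, given channels
white_recording <- function(duration = 10, rate = 1000, n_chan = 1,
                            sd = 1, seed = 1) {
  set.seed(seed)
  samples <- matrix(rnorm(n_chan * duration * rate, sd = sd), nrow = n_chan)
  info <- data.frame(name = c("CA1_R", "CA1_L", "PFC")[seq_len(n_chan)],
                     region = c("CA1", "CA1", "PFC")[seq_len(n_chan)],
                     hemisphere = c("R", "L", "R")[seq_len(n_chan)],
                     stringsAsFactors = FALSE)
  continuous_recording(samples, rate, info)
}

# white-noise recording with bursts of a given z-amplitude injected at
# known times (amplitude in the raw-signal scale, not calibrated)
burst_recording <- function(times, burst_amp = 8, burst_dur = 0.05,
                            duration = 10, rate = 1000, seed = 1) {
  rec <- white_recording(duration, rate, 1, seed = seed)
  nw <- round(burst_dur * rate)
  w <- sin(2 * pi * 120 * (0:(nw - 1)) / rate) * burst_amp
  for (t0 in times) {
    i <- round(t0 * rate) + 1
    rec$samples[1, i:(i + nw - 1)] <- rec$samples[1, i:(i + nw - 1)] + w
  }
  rec
}

# poisson train helper
poisson_train <- function(rate, duration, label = "event", seed = 1) {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  event_train(sort(runif(n, 0, duration)), label, duration,
              warn_unsorted = FALSE)
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
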