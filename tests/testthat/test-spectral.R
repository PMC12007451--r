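test_that("multitaper PSD localizes a tone and conserves its power", {
  rate <- 1000
  t <- (0:(60 * rate - 1)) / rate
  psd <- multitaper_psd(sin(2 * pi * 8 * t), rate)
  df <- diff(psd$freqs[1:2])
  expect_equal(psd$freqs[which.max(psd$power)], 8, tolerance = df)
  # a unit sinusoid has variance 1/2; oracle: plain averaged periodogram
  expect_equal(sum(psd$power) * df, 0.5, tolerance = 0.02)
  seg <- 5000
  starts <- seq(1, length(t) - seg + 1, by = seg)
  pg <- rowMeans(vapply(starts, function(s) {
    xs <- sin(2 * pi * 8 * t[s:(s + seg - 1)])
    (Mod(fft(xs - mean(xs)))^2 / seg / rate)[1:(seg / 2 + 1)]
  }, numeric(seg / 2 + 1)))
  int_oracle <- (2 * sum(pg) - pg[1] - pg[seg / 2 + 1]) * rate / seg
  expect_equal(sum(psd$power) * df, int_oracle, tolerance = 0.02)
})

test_that("white-noise spectrum is flat at the known density", {
  set.seed(11)
  rate <- 1000
  x <- rnorm(60 * rate, sd = 2)
  psd <- multitaper_psd(x, rate)
  expect_true(all(psd$power >= 0))
  level <- 4 / (rate / 2)  # variance spread over one-sided bandwidth
  expect_equal(mean(psd$power[psd$freqs > 5]), level, tolerance = 0.05 * level)
  # Parseval within taper bias, over several noise draws
  for (seed in 1:3) {
    set.seed(seed)
    y <- rnorm(30 * rate)
    p <- multitaper_psd(y, rate)
    expect_equal(sum(p$power) * diff(p$freqs[1:2]), var(y), tolerance = 0.05)
  }
})

test_that("PSD input contracts are enforced and zero maps to zero", {
  rate <- 1000
  expect_error(multitaper_psd(rnorm(1000), rate))         # < one segment
  expect_error(multitaper_psd(rnorm(10 * rate), rate, tw = 3, n_tapers = 6))
  p0 <- multitaper_psd(rep(0, 10 * rate), rate)
  expect_true(all(p0$power == 0))
})

test_that("coherence is exact for identical signals and small when independent", {
  rate <- 250
  set.seed(5)
  x <- rnorm(60 * rate)
  ci <- multitaper_coherence(x, x, rate)
  expect_true(all(abs(ci$coherence - 1) < 1e-9))
  y <- rnorm(60 * rate)
  c0 <- multitaper_coherence(x, y, rate)
  expect_true(all(c0$coherence >= 0 & c0$coherence <= 1))
  bias <- 1 / (c0$n_segments * c0$params$n_tapers)
  expect_lt(mean(c0$coherence), 0.1)
  expect_lt(mean(c0$coherence), 4 * bias)
  # scale invariance
  c_s <- multitaper_coherence(3.7 * x, 0.2 * y, rate)
  expect_equal(c_s$coherence, c0$coherence, tolerance = 1e-9)
  expect_error(multitaper_coherence(rnorm(300), rnorm(300), rate))
})

test_that("shared-sinusoid coherence matches the Monte-Carlo oracle", {
  # frozen oracle: 10,000 independent 2-s segments, x = s + n1, y = s + n2,
  # s a unit 8-Hz sine, noise variance 1/2 (equal power) -> coherence at
  # the 8-Hz bin 0.9304
  rate <- 250
  set.seed(21)
  t <- (0:(60 * rate - 1)) / rate
  s <- sin(2 * pi * 8 * t)
  x <- s + rnorm(length(t), 0, sqrt(0.5))
  y <- s + rnorm(length(t), 0, sqrt(0.5))
  coh <- multitaper_coherence(x, y, rate)
  at8 <- coh$coherence[which.min(abs(coh$freqs - 8))]
  expect_equal(at8, 0.9304, tolerance = 0.05)
})

test_that("band averages honour half-open bands and error when empty", {
  flat <- list(freqs = seq(0, 100, by = 0.5), power = rep(3.3, 201))
  ba <- band_average(flat)
  expect_true(all(abs(ba - 3.3) < 1e-12))
  short <- list(freqs = seq(0, 5, by = 0.5), power = rep(1, 11))
  expect_error_class(band_average(short), "empty_band_error")
  # theta-dominant synthetic LFP
  sim <- gen_lfp(synthesis_spec(duration = 60, seed = 2))
  psd <- multitaper_psd(get_channel(sim$recording, "CA1_R"), 1000)
  ba2 <- band_average(psd)
  expect_gt(ba2[["theta"]], ba2[["fast_gamma"]])
})

test_that("Morlet spectrogram tracks stationary and swept frequencies", {
  rate <- 250
  t <- (0:(20 * rate - 1)) / rate
  sg <- morlet_spectrogram(sin(2 * pi * 8 * t), rate, freqs = c(4, 8, 16))
  valid <- !is.na(sg$power[2, ])
  expect_gt(mean(valid), 0.9)
  ridge <- apply(sg$power[, valid], 2, which.max)
  expect_true(all(ridge == 2))
  # ridge power constant over time for a stationary tone
  p8 <- sg$power[2, valid]
  expect_lt(sd(p8) / mean(p8), 0.05)
  # linear chirp 5 -> 40 Hz; short-time FFT oracle replaced by the known
  # instantaneous frequency of the chirp
  f0 <- 5; f1 <- 40; dur <- 20
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2))
  fr <- seq(4, 44, by = 2)
  sgc <- morlet_spectrogram(chirp, rate, fr)
  for (tt in c(5, 10, 15)) {
    i <- round(tt * rate)
    f_inst <- f0 + (f1 - f0) * tt / dur
    expect_lt(abs(fr[which.max(sgc$power[, i])] - f_inst), 2.1)
  }
  z <- morlet_spectrogram(rep(0, 5 * rate), rate, c(8, 16))
  expect_true(all(z$power == 0 | is.na(z$power)))
  expect_error(morlet_spectrogram(rnorm(1000), rate, freqs = 200))
})

test_that("estimator variance shrinks with the number of tapers", {
  rate <- 200
  est <- function(k, seed) {
    set.seed(seed)
    p <- multitaper_psd(rnorm(8 * rate), rate, segment_ms = 1000,
                        overlap_ms = 0, tw = 3, n_tapers = k)
    p$power[which.min(abs(p$freqs - 30))]
  }
  v1 <- var(vapply(1:40, function(s) est(1, s), numeric(1)))
  v5 <- var(vapply(1:40, function(s) est(5, s), numeric(1)))
  expect_gt(v1 / v5, 2.5)
  expect_lt(v1 / v5, 12)
})

test_that("preprocessing downsamples with anti-aliasing and removes drift", {
  cfg <- analysis_config()
  rate <- 4000
  t <- (0:(20 * rate - 1)) / rate
  x <- sin(2 * pi * 8 * t) + 5 + 0.01 * t   # tone + offset + drift
  pp <- preprocess_lfp(x, rate, cfg)
  expect_equal(pp$rate, 1000)
  expect_equal(length(pp$x), 20 * 1000)
  expect_lt(abs(mean(pp$x)), 0.05)
  psd <- multitaper_psd(pp$x, pp$rate)
  expect_equal(psd$freqs[which.max(psd$power)], 8, tolerance = 0.5)
  expect_error(preprocess_lfp(rnorm(1000), rate = 500, cfg))
})
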