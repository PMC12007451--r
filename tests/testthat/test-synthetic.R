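test_that("generation is fully deterministic under the seed", {
  s1 <- gen_lfp(synthesis_spec(duration = 20, seed = 5))
  s2 <- gen_lfp(synthesis_spec(duration = 20, seed = 5))
  s3 <- gen_lfp(synthesis_spec(duration = 20, seed = 6))
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$truth$discharge_times, s2$truth$discharge_times)
  expect_false(identical(s1$recording$samples, s3$recording$samples))
  fed1 <- gen_fed_session(200, seed = 9)
  fed2 <- gen_fed_session(200, seed = 9)
  expect_identical(fed1$trials, fed2$trials)
})

test_that("discharge-free background yields almost no detections at 5 SD", {
  spec <- synthesis_spec(duration = 300, seed = 2,
                         discharges = list(rate = 0, amplitude = 29.6,
                                           duration = 0.44, carrier = 120,
                                           damping = 4))
  sim <- gen_lfp(spec)
  expect_length(sim$truth$discharge_times$CA1_R, 0)
  ds <- detect_discharges(sim$recording, "CA1_R", rescore = TRUE)
  expect_lt(nrow(ds$discharges) / 300, 0.02)
})

test_that("injected discharges are recovered by the detector", {
  spec <- synthesis_spec(duration = 600, seed = 8)
  sim <- gen_lfp(spec)
  inj <- sim$truth$discharge_times$CA1_R
  # injected count is Poisson-like around rate * duration
  expect_gt(length(inj), 0.41 * 600 - 4 * sqrt(0.41 * 600))
  expect_lt(length(inj), 0.41 * 600 + 4 * sqrt(0.41 * 600))
  ds <- detect_discharges(sim$recording, "CA1_R", rescore = TRUE)
  peaks <- ds$discharges$peak_time
  matched <- vapply(inj, function(t0)
    any(peaks >= t0 - 0.1 & peaks <= t0 + spec$discharges$duration + 0.1),
    logical(1))
  expect_gte(mean(matched), 0.9)
})

test_that("amplitude calibration hits targets across the working range", {
  for (target in c(15, 29.6)) {
    spec <- synthesis_spec(duration = 300, seed = 4,
                           discharges = list(rate = 0.41, amplitude = target,
                                             duration = 0.44, carrier = 120,
                                             damping = 4))
    sim <- gen_lfp(spec)
    ds <- detect_discharges(sim$recording, "CA1_R", rescore = TRUE)
    s <- summarize_discharges(ds)
    expect_lt(abs(s$mean_amplitude - target) / target, 0.10)
  }
})

test_that("contralateral discharges appear at the stated lag and probability", {
  spec <- synthesis_spec(duration = 600, seed = 12)
  sim <- gen_lfp(spec)
  tr <- sim$truth$discharge_times
  expect_equal(length(tr$CA1_L) / length(tr$CA1_R),
               spec$propagation$probability, tolerance = 0.1)
  expect_equal(mean(sim$truth$lags), spec$propagation$lag_mean,
               tolerance = 0.01)
  dsl <- detect_discharges(sim$recording, "CA1_L", rescore = TRUE)
  expect_gt(nrow(dsl$discharges), 0.8 * length(tr$CA1_L))
})

test_that("spike generator matches its rate model", {
  ids <- poisson_train(0.4, 600, "discharge", seed = 3)
  # gain 0: homogeneous Poisson at baseline within 3 SE
  sp0 <- gen_spike_train(ids, baseline = 5, gain = 0, kernel_width = 0.2,
                         duration = 600, seed = 1)
  n_exp <- 5 * 600
  expect_lt(abs(length(sp0$times) - n_exp), 3 * sqrt(n_exp))
  # positive gain: positive post-onset z-score in the correlogram
  sp2 <- gen_spike_train(ids, baseline = 5, gain = 2, kernel_width = 0.2,
                         duration = 600, seed = 1)
  cc <- sliding_sweeps(ids, sp2, 1.5, 0.2, n_shuffles = 50, seed = 2)
  post <- cc$values[cc$lag_centers > 0 & cc$lag_centers < 0.4]
  expect_gt(max(post), 3)
  expect_length(gen_spike_train(ids, 5, 2, 0.2, duration = 0)$times, 0)
  expect_error(gen_spike_train(ids, 5, gain = -1.5, 0.2, 600))
  expect_error(gen_spike_train(ids, baseline = 0, 1, 0.2, 600))
})

test_that("speed generator produces the stated multiplicative dip", {
  ids <- poisson_train(0.2, 600, "discharge", seed = 5)
  st0 <- gen_speed_trace(ids, baseline = 8, dip = 0, recovery = 1, seed = 2)
  a0 <- speed_triggered_average(st0, ids, pre_window = 2, post_window = 0.2)
  expect_equal(a0$post_mean / a0$pre_mean, 1, tolerance = 0.05)
  st5 <- gen_speed_trace(ids, baseline = 8, dip = 0.5, recovery = 1, seed = 2)
  a5 <- speed_triggered_average(st5, ids, pre_window = 2, post_window = 0.2)
  # closed form: mean over [0, 0.2] of 1 - 0.5 exp(-t) = 0.547
  expect_equal(a5$post_mean / a5$pre_mean, 0.547, tolerance = 0.08)
  expect_error(gen_speed_trace(ids, baseline = 0, dip = 0.5, recovery = 1))
  expect_error(gen_speed_trace(ids, baseline = 8, dip = 0.5, recovery = 1,
                               fps = 0))
})

test_that("FED simulator respects port probabilities and block structure", {
  fed <- gen_fed_session(10000, policy = list(type = "oracle", p_collect = 1,
                                              latency_mean = 2), seed = 1)
  expect_equal(mean(fed$trials$rewarded), 0.80, tolerance = 0.0125)
  lens <- rle(fed$trials$block)$lengths
  lens <- head(lens, -1)  # last block may be truncated
  expect_true(all(lens >= 13 & lens <= 17))
  # high port actually flips between blocks
  per_block <- tapply(fed$trials$high_port, fed$trials$block, function(h) h[1])
  expect_true(all(per_block[-1] != head(per_block, -1)))
  expect_error(gen_fed_session(0))
  expect_error(gen_fed_session(100, p_high = 1.2))
  expect_error(gen_fed_session(100, block_mean = 2, block_jitter = 5))
})

test_that("training-curve generator recovers its slope by OLS", {
  exact <- gen_training_curves(10, slope = 2, intercept = 1, noise_sd = 0)
  expect_equal(fit_learning_curve(exact)$slope, 2, tolerance = 1e-12)
  slopes <- vapply(1:50, function(i)
    fit_learning_curve(gen_training_curves(10, -3.87, 60, 1, seed = i))$slope,
    numeric(1))
  se <- sd(slopes) / sqrt(50)
  expect_lt(abs(mean(slopes) - (-3.87)), 2 * se + 1e-12)
  expect_error(gen_training_curves(2, 1, 0, 1))
  expect_error(gen_training_curves(10, 1, 0, -1))
})
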