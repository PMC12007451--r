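fed_from <- function(ports, rewarded = NULL, collect = NULL) {
  n <- length(ports)
  if (is.null(rewarded)) rewarded <- rep(FALSE, n)
  structure(list(trials = data.frame(
    time_s = seq_len(n), port = ports, rewarded = rewarded, block = 1L,
    high_port = "left",
    collect_time = if (is.null(collect)) rep(NA_real_, n) else collect,
    stringsAsFactors = FALSE)), class = "fed_log")
}

test_that("session metrics follow their definitions", {
  ports <- rep(c("left", "right"), 5)
  rew <- c(rep(TRUE, 8), FALSE, FALSE)
  collect <- ifelse(rew, seq_len(10) + 2, NA_real_)
  sm <- session_metrics(fed_from(ports, rew, collect))
  expect_equal(sm$nose_pokes, 10)
  expect_equal(sm$pellets, 8)
  expect_equal(sm$efficiency, 0.8)
  expect_equal(sm$mean_latency, 2)
  expect_equal(sm$alternance, 1.0)
  expect_equal(session_metrics(fed_from(c("left", "left", "left")))$alternance, 0)
  # center-only log: efficiency and alternance undefined-flagged
  sm0 <- session_metrics(fed_from(c("center", "center")))
  expect_true(is.na(sm0$efficiency))
  expect_equal(sm0$nose_pokes, 0)
})

test_that("metrics stay in bounds over random logs and the oracle policy pays 80%", {
  for (seed in 1:10) {
    fed <- gen_fed_session(300, seed = seed)
    sm <- session_metrics(fed)
    expect_gte(sm$efficiency, 0); expect_lte(sm$efficiency, 1)
    expect_gte(sm$alternance, 0); expect_lte(sm$alternance, 1)
  }
  fed <- gen_fed_session(10000, policy = list(type = "oracle", p_collect = 1,
                                              latency_mean = 2), seed = 1)
  expect_equal(session_metrics(fed)$efficiency, 0.8, tolerance = 0.0125)
})

test_that("learning-curve fits recover slopes and flag degenerate input", {
  exact <- fit_learning_curve(data.frame(day = 1:6, value = 2 * (1:6) + 1))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$pearson_r, 1, tolerance = 1e-12)
  const <- fit_learning_curve(data.frame(day = 1:5, value = rep(3, 5)))
  expect_true(is.na(const$pearson_r))
  expect_error(fit_learning_curve(data.frame(day = 1:2, value = 1:2)))
  slopes <- vapply(1:50, function(i)
    fit_learning_curve(gen_training_curves(10, 2.77, 10, 1, seed = i))$slope,
    numeric(1))
  expect_lt(abs(mean(slopes) - 2.77), 2 * sd(slopes) / sqrt(50))
})

test_that("bootstrap slope test separates slopes and is seed-stable", {
  a <- gen_training_curves(10, 0, 5, 0.01, seed = 1)
  b <- gen_training_curves(10, 1, 5, 0.01, seed = 2)
  bt <- bootstrap_slope_test(a, b, n_iter = 500, seed = 3)
  expect_lt(bt$p, 0.05)
  same <- bootstrap_slope_test(a, a, n_iter = 500, seed = 4)
  expect_gte(same$p, 0.5)
  again <- bootstrap_slope_test(a, b, n_iter = 500, seed = 3)
  expect_identical(bt$p, again$p)
  expect_error(bootstrap_slope_test(a[1:2, ], b))
})

test_that("bootstrap test holds its size under the null", {
  rejections <- vapply(1:200, function(i) {
    a <- gen_training_curves(8, 1, 0, 1, seed = 2 * i)
    b <- gen_training_curves(8, 1, 0, 1, seed = 2 * i + 1)
    bootstrap_slope_test(a, b, n_iter = 400, seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("discrimination index is antisymmetric, bounded and exact", {
  expect_equal(discrimination_index(60, 60), 0)
  expect_equal(discrimination_index(78, 122), 0.22)
  expect_equal(discrimination_index(122, 78), -0.22)
  expect_equal(discrimination_index(50, 0), -1)
  expect_equal(discrimination_index(0, 50), 1)
  for (i in 1:20) {
    set.seed(i)
    s <- runif(1, 0, 100); tt <- runif(1, 0, 100)
    di <- discrimination_index(s, tt)
    expect_gte(di, -1); expect_lte(di, 1)
    expect_equal(discrimination_index(tt, s), -di)
  }
  expect_error_class(discrimination_index(0, 0), "degenerate_input_error")
  expect_error(discrimination_index(-1, 5))
})

test_that("engagement segmentation applies the zone and speed criterion", {
  n <- 300
  st <- speed_trace((0:(n - 1)) / 30, rep(5, n), 30)
  pos <- data.frame(x = rep(1, n), y = rep(1, n))
  seg <- segment_engagement(pos, st, fed_zone = c(0, 0, 2, 2))
  expect_equal(nrow(seg$engaged), 1)
  expect_equal(seg$engaged$end - seg$engaged$start, n / 30, tolerance = 0.05)
  # a large speed excursion inside the zone is excluded
  sp <- rep(5, n); sp[150] <- 500
  sp <- sp + rnorm(n, 0, 0.1)
  st2 <- speed_trace((0:(n - 1)) / 30, pmax(sp, 0), 30)
  seg2 <- segment_engagement(pos, st2, fed_zone = c(0, 0, 2, 2))
  gaps <- nrow(seg2$engaged)
  expect_gte(gaps, 2)
  covered <- sum(seg2$engaged$end - seg2$engaged$start)
  expect_lt(covered, n / 30)
  expect_warning(segment_engagement(pos, st, fed_zone = c(10, 10, 12, 12)),
                 "never visited")
})

test_that("engagement recall is high on synthetic in-zone episodes", {
  set.seed(5)
  fps <- 30; dur <- 120; n <- dur * fps
  t <- (0:(n - 1)) / fps
  # alternate 10-s visits to the feeder corner with 10-s arena excursions
  in_zone_truth <- (floor(t / 10) %% 2) == 0
  x <- ifelse(in_zone_truth, 1 + rnorm(n, 0, 0.2), 20 + rnorm(n, 0, 3))
  y <- ifelse(in_zone_truth, 1 + rnorm(n, 0, 0.2), 15 + rnorm(n, 0, 3))
  sp <- ifelse(in_zone_truth, abs(rnorm(n, 2, 0.5)), abs(rnorm(n, 12, 3)))
  st <- speed_trace(t, sp, fps)
  seg <- segment_engagement(data.frame(x = x, y = y), st,
                            fed_zone = c(-1, -1, 3, 3))
  engaged_mask <- rep(FALSE, n)
  for (i in seq_len(nrow(seg$engaged)))
    engaged_mask[t >= seg$engaged$start[i] & t < seg$engaged$end[i]] <- TRUE
  recall <- mean(engaged_mask[in_zone_truth])
  expect_gte(recall, 0.95)
  precision <- mean(in_zone_truth[engaged_mask])
  expect_gte(precision, 0.95)
})
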