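#' Per-session operant metrics from a FED log
#'
#' Counts, pellet-collection latency, efficiency (pellets collected per
#' nose poke) and alternance (fraction of consecutive lateral pokes on
#' different ports).
#'
#' @param log a \code{fed_log} (see \code{\link{gen_fed_session}} /
#'   \code{\link{read_fed_log}}).
#' @return list of class \code{session_metrics}: \code{nose_pokes},
#'   \code{pellets}, \code{mean_latency} (s, NA when nothing collected),
#'   \code{efficiency}, \code{alternance}.
#' @export
session_metrics <- function(log) {
  tr <- log$trials
  assert_that(nrow(tr) > 0, "empty FED log")
  lateral <- tr[tr$port %in% c("left", "right"), , drop = FALSE]
  n_pokes <- nrow(lateral)
  collected <- !is.na(lateral$collect_time) & lateral$rewarded
  n_pellets <- sum(collected)
  latency <- if (n_pellets)
    mean(lateral$collect_time[collected] - lateral$time_s[collected])
    else NA_real_
  efficiency <- if (n_pokes) n_pellets / n_pokes else NA_real_
  alternance <- if (n_pokes >= 2)
    mean(lateral$port[-1] != lateral$port[-n_pokes]) else NA_real_
  structure(list(nose_pokes = n_pokes, pellets = n_pellets,
                 mean_latency = latency, efficiency = efficiency,
                 alternance = alternance),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> %d pokes, %d pellets, latency %.2f s, efficiency %.3f, alternance %.3f\n",
              x$nose_pokes, x$pellets, x$mean_latency, x$efficiency,
              x$alternance))
  invisible(x)
}

#' Ordinary least-squares learning-curve fit
#'
#' Fits \code{value ~ day} and reports the slope, intercept, Pearson
#' correlation and its two-sided p-value.
#'
#' @param series data.frame with \code{day} and \code{value} (>= 3 days),
#'   or a numeric vector of per-day values (days taken as 1..n).
#' @return list: \code{slope}, \code{intercept}, \code{pearson_r}, \code{p}.
#'   For a constant series the correlation is NA-flagged.
#' @export
fit_learning_curve <- function(series) {
  if (is.numeric(series)) series <- data.frame(day = seq_along(series),
                                               value = series)
  assert_that(nrow(series) >= 3, "need at least 3 days")
  fit <- stats::lm(value ~ day, data = series)
  cf <- stats::coef(fit)
  if (stats::sd(series$value) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(series$day, series$value)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       pearson_r = r, p = p)
}

#' Bootstrap comparison of two learning-curve slopes
#'
#' Case-resamples (day, value) pairs with replacement within each group,
#' refits the OLS slope per resample, and reports the two-sided p-value as
#' the doubled one-sided tail fraction of the slope-difference distribution
#' crossing zero (capped at 1). Degenerate resamples (all one day) are
#' redrawn and counted.
#'
#' @param series_a,series_b data.frames with \code{day}, \code{value}
#'   (each >= 3 points).
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return list: \code{p}, \code{slopes_a}, \code{slopes_b},
#'   \code{observed_diff}, \code{n_redrawn}.
#' @export
bootstrap_slope_test <- function(series_a, series_b, n_iter = 1000, seed = 1) {
  if (is.numeric(series_a)) series_a <- data.frame(day = seq_along(series_a),
                                                   value = series_a)
  if (is.numeric(series_b)) series_b <- data.frame(day = seq_along(series_b),
                                                   value = series_b)
  assert_that(nrow(series_a) >= 3 && nrow(series_b) >= 3,
              "both series need at least 3 points")
  slope_of <- function(d) {
    sxx <- sum((d$day - mean(d$day))^2)
    if (sxx == 0) return(NA_real_)
    sum((d$day - mean(d$day)) * (d$value - mean(d$value))) / sxx
  }
  n_redrawn <- 0L
  res <- with_seed(seed, {
    draw <- function(d) {
      repeat {
        s <- d[sample.int(nrow(d), replace = TRUE), ]
        sl <- slope_of(s)
        if (!is.na(sl)) return(sl)
        n_redrawn <<- n_redrawn + 1L
      }
    }
    sa <- vapply(seq_len(n_iter), function(i) draw(series_a), numeric(1))
    sb <- vapply(seq_len(n_iter), function(i) draw(series_b), numeric(1))
    list(sa = sa, sb = sb)
  })
  diffs <- res$sa - res$sb
  tail_lo <- mean(diffs <= 0)
  tail_hi <- mean(diffs >= 0)
  p <- min(1, 2 * min(tail_lo, tail_hi))
  list(p = p, slopes_a = res$sa, slopes_b = res$sb,
       observed_diff = slope_of(series_a) - slope_of(series_b),
       n_redrawn = n_redrawn)
}

#' Discrimination index for the metric spatial-change task
#'
#' \code{DI = (test - sample) / (test + sample)} on total object-exploration
#' times; positive values indicate increased exploration after the spatial
#' change, i.e. detection of the new object configuration.
#'
#' @param sample_time total exploration time in the sample trial, s (>= 0).
#' @param test_time total exploration time in the test trial, s (>= 0).
#' @return DI in [-1, 1].
#' @export
discrimination_index <- function(sample_time, test_time) {
  assert_that(all(sample_time >= 0) && all(test_time >= 0),
              "exploration times must be non-negative")
  tot <- sample_time + test_time
  assert_that(all(tot > 0), "both exploration times are zero: DI undefined",
              "degenerate_input_error")
  (test_time - sample_time) / tot
}

#' Segment task-engaged episodes from position and speed
#'
#' Frames inside the feeder zone whose speed lies within
#' \code{speed_sd_limit} standard deviations of the mean in-zone speed are
#' engaged; contiguous engaged frames are merged into half-open intervals.
#'
#' @param positions data.frame with \code{x}, \code{y} per frame (same
#'   frames as \code{speed}).
#' @param speed a \code{\link{speed_trace}}.
#' @param fed_zone rectangle \code{c(x0, y0, x1, y1)}.
#' @param speed_sd_limit SD window around the in-zone mean speed (default 2).
#' @return object of class \code{engagement_segmentation}: \code{engaged}
#'   (data.frame start/end, s), \code{non_engaged}, \code{criterion}.
#' @export
segment_engagement <- function(positions, speed, fed_zone,
                               speed_sd_limit = 2) {
  assert_that(length(fed_zone) == 4 && fed_zone[1] < fed_zone[3] &&
              fed_zone[2] < fed_zone[4], "fed_zone must be c(x0,y0,x1,y1)")
  n <- length(speed$speed)
  assert_that(nrow(positions) == n, "positions and speed must align by frame")
  in_zone <- positions$x >= fed_zone[1] & positions$x <= fed_zone[3] &
             positions$y >= fed_zone[2] & positions$y <= fed_zone[4]
  if (!any(in_zone)) {
    warning("feeder zone never visited; empty segmentation")
    return(structure(list(
      engaged = data.frame(start = numeric(0), end = numeric(0)),
      non_engaged = data.frame(start = speed$frame_times[1],
                               end = speed$frame_times[n] + 1 / speed$fps),
      criterion = list(zone = fed_zone, speed_mean = NA_real_,
                       speed_sd = NA_real_, limit = speed_sd_limit)),
      class = "engagement_segmentation"))
  }
  mu <- mean(speed$speed[in_zone])
  sdv <- stats::sd(speed$speed[in_zone])
  if (!is.finite(sdv)) sdv <- 0
  engaged <- in_zone & abs(speed$speed - mu) <= speed_sd_limit * sdv
  to_intervals <- function(mask) {
    r <- runs_of(mask)
    if (nrow(r) == 0L) return(data.frame(start = numeric(0), end = numeric(0)))
    data.frame(start = speed$frame_times[r[, "start"]],
               end = speed$frame_times[r[, "end"]] + 1 / speed$fps)
  }
  structure(list(engaged = to_intervals(engaged),
                 non_engaged = to_intervals(!engaged),
                 criterion = list(zone = fed_zone, speed_mean = mu,
                                  speed_sd = sdv, limit = speed_sd_limit)),
            class = "engagement_segmentation")
}

#' @export
print.engagement_segmentation <- function(x, ...) {
  cat(sprintf("<engagement_segmentation> %d engaged interval(s), %.1f s total\n",
              nrow(x$engaged), sum(x$engaged$end - x$engaged$start)))
  invisible(x)
}
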