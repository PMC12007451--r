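#' Uniformly sampled locomotion speed trace
#'
#' @param frame_times frame times in seconds (uniform spacing 1/fps).
#' @param speed non-negative speeds, cm/s.
#' @param fps frame rate, Hz.
#' @return object of class \code{speed_trace}.
#' @export
speed_trace <- function(frame_times, speed, fps) {
  assert_that(length(frame_times) == length(speed),
              "times and speeds must have equal length")
  assert_that(all(speed >= 0), "speed must be non-negative")
  if (length(frame_times) > 2) {
    dt <- diff(frame_times)
    assert_that(max(abs(dt - 1 / fps)) < 1e-6, "frame spacing must be 1/fps")
  }
  structure(list(frame_times = frame_times, speed = speed, fps = fps),
            class = "speed_trace")
}

#' @export
print.speed_trace <- function(x, ...) {
  cat(sprintf("<speed_trace> %d frames @ %g fps, mean %.2f cm/s\n",
              length(x$speed), x$fps, mean(x$speed)))
  invisible(x)
}

bin_counts_around <- function(ref, target, window, bin) {
  n_bins <- length(seq(-window, window, by = bin)) - 1L
  acc <- numeric(n_bins)
  for (r in ref) {
    lo <- findInterval(r - window, target) + 1L
    hi <- findInterval(r + window - 1e-12, target)
    if (hi < lo) next
    rel <- target[lo:hi] - r
    idx <- floor((rel + window) / bin) + 1L
    idx <- idx[idx >= 1L & idx <= n_bins]
    acc <- acc + tabulate(idx, nbins = n_bins)
  }
  acc / length(ref)
}

#' Sliding-sweeps peri-event cross-correlogram
#'
#' For each reference event, target timestamps within \code{+/- window} are
#' binned relative to the reference onset; the per-reference templates are
#' averaged and expressed in z-score units against a surrogate distribution
#' obtained by circularly shifting the target train (uniform random shifts,
#' seeded). Reference events whose window falls outside the recording are
#' dropped and counted.
#'
#' @param reference an \code{\link{event_train}} (e.g. discharge onsets).
#' @param target an \code{event_train} (e.g. contralateral discharges or
#'   spikes).
#' @param window half-window, s (0.5 for discharge-discharge, 1.5 for
#'   discharge-spike).
#' @param bin bin width, s (0.1 and 0.2 respectively).
#' @param n_shuffles circular-shift surrogates (default 100).
#' @param seed RNG seed for the shifts.
#' @param normalize "surrogate" (z-scores, default) or "rate" (mean counts
#'   divided by the target's mean rate per bin).
#' @return object of class \code{crosscorrelogram}: \code{lag_bin_edges},
#'   \code{lag_centers}, \code{values}, \code{n_reference},
#'   \code{n_dropped}, \code{raw} (mean counts per bin).
#' @export
sliding_sweeps <- function(reference, target, window, bin, n_shuffles = 100,
                           seed = 1, normalize = c("surrogate", "rate")) {
  normalize <- match.arg(normalize)
  assert_that(length(reference$times) >= 1, "empty reference train")
  assert_that(bin <= window, "bin width must not exceed the window")
  dur <- max(reference$duration, target$duration)
  usable <- reference$times >= window & reference$times <= dur - window
  n_dropped <- sum(!usable)
  ref <- reference$times[usable]
  assert_that(length(ref) >= 1, "no reference events with a full window")
  raw <- bin_counts_around(ref, target$times, window, bin)
  edges <- seq(-window, window, by = bin)
  values <- if (normalize == "rate") {
    expected <- length(target$times) / dur * bin
    raw / expected
  } else {
    surr <- with_seed(seed, {
      vapply(seq_len(n_shuffles), function(s) {
        shift <- stats::runif(1, 0, dur)
        shifted <- sort((target$times + shift) %% dur)
        bin_counts_around(ref, shifted, window, bin)
      }, numeric(length(raw)))
    })
    mu <- rowMeans(surr)
    sdv <- apply(surr, 1, stats::sd)
    sdv[sdv == 0] <- NA_real_
    (raw - mu) / sdv
  }
  structure(list(lag_bin_edges = edges,
                 lag_centers = edges[-length(edges)] + bin / 2,
                 values = values, raw = raw,
                 n_reference = length(ref), n_dropped = n_dropped,
                 normalize = normalize),
            class = "crosscorrelogram")
}

#' @export
print.crosscorrelogram <- function(x, ...) {
  cat(sprintf("<crosscorrelogram> %d bins in [%g, %g] s, %d references (%s-normalized)\n",
              length(x$values), min(x$lag_bin_edges), max(x$lag_bin_edges),
              x$n_reference, x$normalize))
  invisible(x)
}

#' Instantaneous locomotion speed from a tracked trajectory
#'
#' Smooths x and y with a moving average (10 successive points by default),
#' then takes the per-frame Euclidean displacement times the frame rate.
#' Gaps of up to \code{max_gap} missing frames are linearly interpolated.
#'
#' @param track data.frame with columns \code{frame}, \code{x}, \code{y}
#'   (pixels), or a CSV path to one.
#' @param fps camera frame rate (default 30).
#' @param smooth_window moving-average length in points (default 10).
#' @param px_per_cm pixel-to-centimetre scale (> 0).
#' @param max_gap largest interpolatable gap in frames (default 5).
#' @return a \code{\link{speed_trace}} (length \code{nrow(track) - 1}).
#' @export
compute_speed <- function(track, fps = 30, smooth_window = 10, px_per_cm = 1,
                          max_gap = 5) {
  if (is.character(track)) track <- utils::read.csv(track)
  assert_that(all(c("frame", "x", "y") %in% names(track)),
              "track needs frame, x, y columns", "format_error")
  assert_that(px_per_cm > 0, "px_per_cm must be positive")
  assert_that(nrow(track) >= smooth_window + 1,
              "need at least smooth_window + 1 frames", "too_short_error")
  frames <- track$frame
  full <- seq(min(frames), max(frames))
  if (length(full) > nrow(track)) {
    gaps <- diff(frames) - 1L
    assert_that(max(gaps) <= max_gap,
                sprintf("gap of %d frames exceeds the %d-frame limit",
                        max(gaps), max_gap), "gap_error")
    x <- stats::approx(frames, track$x, xout = full)$y
    y <- stats::approx(frames, track$y, xout = full)$y
  } else {
    x <- track$x; y <- track$y
  }
  xs <- moving_average(x, smooth_window)
  ys <- moving_average(y, smooth_window)
  disp <- sqrt(diff(xs)^2 + diff(ys)^2)
  sp <- disp * fps / px_per_cm
  speed_trace((full[-1] - full[1]) / fps, sp, fps)
}

#' Event-triggered locomotion speed average
#'
#' Averages the speed trace around each event onset and summarizes the
#' pre- and post-onset window means. Events whose window exceeds the trace
#' are excluded and counted.
#'
#' @param speed a \code{\link{speed_trace}}.
#' @param events an \code{\link{event_train}} (e.g. discharge onsets).
#' @param pre_window,post_window window lengths, s (defaults 2 each).
#' @return list: \code{lag_times}, \code{mean_curve}, \code{pre_mean},
#'   \code{post_mean}, \code{pairs} (per-event pre/post means),
#'   \code{n_events}, \code{n_dropped}.
#' @export
speed_triggered_average <- function(speed, events, pre_window = 2,
                                    post_window = 2) {
  ft <- speed$frame_times
  t0 <- ft[1]; t1 <- ft[length(ft)]
  usable <- events$times - pre_window >= t0 & events$times + post_window <= t1
  assert_that(any(usable), "no events with a full pre/post window")
  ev <- events$times[usable]
  fps <- speed$fps
  n_pre <- round(pre_window * fps)
  n_post <- round(post_window * fps)
  curves <- vapply(ev, function(e) {
    i0 <- which.min(abs(ft - e))
    speed$speed[(i0 - n_pre):(i0 + n_post)]
  }, numeric(n_pre + n_post + 1L))
  pre_idx <- seq_len(n_pre)
  post_idx <- (n_pre + 2L):(n_pre + n_post + 1L)
  pairs <- data.frame(pre = colMeans(curves[pre_idx, , drop = FALSE]),
                      post = colMeans(curves[post_idx, , drop = FALSE]))
  list(lag_times = (-n_pre:n_post) / fps,
       mean_curve = rowMeans(curves),
       pre_mean = mean(pairs$pre), post_mean = mean(pairs$post),
       pairs = pairs, n_events = length(ev), n_dropped = sum(!usable))
}
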