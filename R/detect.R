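#' Interictal-discharge detection statistic
#'
#' High-pass filters the signal (Butterworth, zero-phase forward-backward),
#' squares it, and z-scores the squared signal against its whole-trace mean
#' and standard deviation. Large-amplitude broadband transients stand out as
#' extreme positive excursions of this statistic.
#'
#' @param x single-channel numeric signal.
#' @param rate sampling rate, Hz (must exceed twice the cutoff).
#' @param hp_cutoff high-pass cutoff in Hz (default 40).
#' @param order Butterworth order (default 4).
#' @param baseline_mask optional logical vector (TRUE = include sample in
#'   the mean/SD baseline); used by the event-excluded re-scoring pass.
#' @return numeric vector, the per-sample z-scored squared signal.
#' @export
detection_statistic <- function(x, rate, hp_cutoff = 40, order = 4,
                                baseline_mask = NULL) {
  assert_that(rate > 2 * hp_cutoff, "sampling rate must exceed twice the cutoff")
  assert_that(length(x) > 3 * (order + 1) * 3, "signal too short for filter warm-up",
              "too_short_error")
  if (stats::sd(x) == 0)
    stop_ictalysis("degenerate input: constant signal", "degenerate_input_error")
  bf <- signal::butter(order, hp_cutoff / (rate / 2), type = "high")
  # reflect-pad so forward-backward filter transients die out off-signal
  n <- length(x)
  pad <- min(n - 1L, round(rate))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  hp <- as.numeric(signal::filtfilt(bf, xp))[(pad + 1L):(pad + n)]
  sq <- hp^2
  base <- if (is.null(baseline_mask)) sq else sq[baseline_mask]
  m <- mean(base)
  s <- stats::sd(base)
  if (!is.finite(s) || s == 0)
    stop_ictalysis("degenerate input: squared signal has zero variance",
                   "degenerate_input_error")
  (sq - m) / s
}

# contiguous runs of TRUE as an integer matrix [start, end] (inclusive)
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# walk outward from peak_idx while `below` runs stay shorter than gap_samp
walk_extent <- function(below, peak_idx, gap_samp, n) {
  on_idx <- peak_idx; i <- peak_idx; run <- 0L
  while (i > 1L) {
    i <- i - 1L
    if (below[i]) { run <- run + 1L; if (run >= gap_samp) break }
    else { run <- 0L; on_idx <- i }
  }
  off_idx <- peak_idx; i <- peak_idx; run <- 0L
  while (i < n) {
    i <- i + 1L
    if (below[i]) { run <- run + 1L; if (run >= gap_samp) break }
    else { run <- 0L; off_idx <- i }
  }
  c(on_idx, off_idx)
}

events_from_statistic <- function(z, rate, threshold, merge_gap, boundary,
                                  min_duration, extent_smooth,
                                  mask_boundary = 0.5) {
  regions <- runs_of(z > threshold)
  if (nrow(regions) == 0L)
    return(data.frame(onset = numeric(0), peak_time = numeric(0),
                      amplitude = numeric(0), duration = numeric(0),
                      onset_idx = integer(0), offset_idx = integer(0),
                      mask_on = integer(0), mask_off = integer(0)))
  # merge candidate regions separated by less than merge_gap
  gap_samp <- round(merge_gap * rate)
  merged <- list(regions[1L, ])
  if (nrow(regions) > 1L) for (i in 2:nrow(regions)) {
    last <- merged[[length(merged)]]
    if (regions[i, "start"] - last["end"] <= gap_samp)
      merged[[length(merged)]]["end"] <- regions[i, "end"]
    else merged[[length(merged) + 1L]] <- regions[i, ]
  }
  zs <- moving_average(z, max(1L, round(extent_smooth * rate)))
  n <- length(z)
  below <- zs < boundary
  below_mask <- zs < mask_boundary
  rows <- lapply(merged, function(rg) {
    seg <- rg["start"]:rg["end"]
    peak_idx <- seg[which.max(z[seg])]
    # extent: walk outward from the peak on the smoothed statistic until it
    # stays below the boundary level for at least merge_gap (transient
    # sub-boundary dips from carrier/background beating are bridged); a
    # second, low-water-mark extent delimits baseline contamination for the
    # re-scoring pass
    ext <- walk_extent(below, peak_idx, gap_samp, n)
    mext <- walk_extent(below_mask, peak_idx, gap_samp, n)
    data.frame(onset = (ext[1] - 1L) / rate,
               peak_time = (peak_idx - 1L) / rate,
               amplitude = z[peak_idx],
               duration = (ext[2] - ext[1] + 1L) / rate,
               onset_idx = ext[1], offset_idx = ext[2],
               mask_on = mext[1], mask_off = mext[2])
  })
  ev <- do.call(rbind, rows)
  ev <- ev[ev$duration >= min_duration, , drop = FALSE]
  # fragments of one physiological event share a low-water-mark extent;
  # keep the largest peak of each overlapping group
  if (nrow(ev) > 1L) {
    keep <- rep(TRUE, nrow(ev))
    for (i in 2:nrow(ev)) {
      j <- max(which(keep[seq_len(i - 1L)]))
      if (ev$mask_on[i] <= ev$mask_off[j]) {
        if (ev$amplitude[i] > ev$amplitude[j]) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
    ev <- ev[keep, , drop = FALSE]
  }
  ev
}

#' Detect interictal discharges on one channel
#'
#' Contiguous regions of the detection statistic above \code{threshold}
#' become candidate events; candidates closer than \code{merge_gap} are
#' merged; each event's extent is then grown outward from its peak to where
#' a lightly smoothed copy of the statistic falls below \code{boundary}
#' standard deviations, and events shorter than \code{min_duration} are
#' rejected as glitches. With \code{rescore = TRUE} a single refinement pass
#' re-estimates the baseline mean/SD from non-event samples and repeats the
#' detection — appropriate for heavy-discharge recordings where the events
#' themselves inflate the whole-trace baseline.
#'
#' @param rec a \code{\link{continuous_recording}}.
#' @param channel channel name to analyze.
#' @param threshold detection threshold in SD (default 5).
#' @param merge_gap merge gap in seconds (default 0.05).
#' @param boundary extent boundary in SD (default 2).
#' @param hp_cutoff,order high-pass settings (defaults 40 Hz, 4).
#' @param min_duration minimum event duration in s (default 0.01).
#' @param extent_smooth moving-average window (s) used only for the extent
#'   boundary walk (default 0.02).
#' @param rescore if TRUE, one event-excluded baseline refinement pass.
#' @return object of class \code{discharge_set}: data.frame
#'   \code{discharges} (onset, peak_time, amplitude, duration), channel,
#'   params, recording_duration.
#' @export
detect_discharges <- function(rec, channel, threshold = 5, merge_gap = 0.05,
                              boundary = 2, hp_cutoff = 40, order = 4,
                              min_duration = 0.01, extent_smooth = 0.02,
                              rescore = FALSE) {
  assert_that(inherits(rec, "continuous_recording"), "rec must be a continuous_recording")
  x <- get_channel(rec, channel)
  assert_that(length(x) > 0, "empty recording")
  rate <- rec$sample_rate
  z <- detection_statistic(x, rate, hp_cutoff, order)
  ev <- events_from_statistic(z, rate, threshold, merge_gap, boundary,
                              min_duration, extent_smooth)
  if (rescore && nrow(ev) > 0L) {
    # iterate the event-excluded re-scoring to a fixed point: each pass
    # lengthens the masked extents, deflating the baseline SD until the
    # z-amplitudes stabilize (heavy-discharge recordings need 2-3 passes)
    pad <- round(merge_gap * rate)
    for (pass in 1:3) {
      prev_amp <- mean(ev$amplitude)
      prev_n <- nrow(ev)
      mask <- rep(TRUE, length(x))
      for (i in seq_len(nrow(ev)))
        mask[max(1L, ev$mask_on[i] - pad):min(length(x), ev$mask_off[i] + pad)] <- FALSE
      if (sum(mask) <= rate) break  # need a non-trivial baseline
      z <- detection_statistic(x, rate, hp_cutoff, order, baseline_mask = mask)
      ev <- events_from_statistic(z, rate, threshold, merge_gap, boundary,
                                  min_duration, extent_smooth)
      if (nrow(ev) == 0L) break
      if (nrow(ev) == prev_n &&
          abs(mean(ev$amplitude) - prev_amp) < 0.02 * prev_amp) break
    }
  }
  structure(
    list(discharges = ev[, c("onset", "peak_time", "amplitude", "duration")],
         channel = channel,
         params = list(hp_cutoff = hp_cutoff, order = order,
                       threshold = threshold, merge_gap = merge_gap,
                       boundary = boundary, min_duration = min_duration,
                       extent_smooth = extent_smooth, rescore = rescore),
         recording_duration = recording_duration(rec)),
    class = "discharge_set")
}

#' @export
print.discharge_set <- function(x, ...) {
  cat(sprintf("<discharge_set> %d events on '%s' over %.1f s (%.3f Hz)\n",
              nrow(x$discharges), x$channel, x$recording_duration,
              nrow(x$discharges) / x$recording_duration))
  invisible(x)
}

#' Convert detected discharges to an event train of onsets
#' @param ds a \code{discharge_set}.
#' @param use one of "onset" or "peak_time".
#' @return an \code{\link{event_train}}.
#' @export
discharge_train <- function(ds, use = c("onset", "peak_time")) {
  use <- match.arg(use)
  event_train(ds$discharges[[use]], label = "discharge",
              duration = ds$recording_duration)
}

#' Summarize a discharge set
#'
#' @param ds a \code{discharge_set}.
#' @return list: \code{density} (events/s), \code{mean_amplitude} (z),
#'   \code{mean_duration} (s), \code{count}. Means are NA for an empty set.
#' @export
summarize_discharges <- function(ds) {
  assert_that(ds$recording_duration > 0, "recording_duration must be positive")
  d <- ds$discharges
  list(density = nrow(d) / ds$recording_duration,
       mean_amplitude = if (nrow(d)) mean(d$amplitude) else NA_real_,
       mean_duration = if (nrow(d)) mean(d$duration) else NA_real_,
       count = nrow(d))
}
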