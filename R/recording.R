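#' Multi-channel continuous recording
#'
#' Container for a sampled multi-channel local field potential signal with
#' per-channel anatomical labels. Samples are stored as a channels x time
#' matrix of voltages (microvolts by convention; all analyses are
#' scale-invariant where the underlying statistic is).
#'
#' @param samples numeric matrix, channels x time.
#' @param sample_rate sampling rate in Hz (positive).
#' @param channel_info data.frame with columns \code{name}, \code{region}
#'   (one of CA1, PFC, PPC) and \code{hemisphere} (L or R), one row per
#'   channel.
#' @param start_time recording start in seconds (default 0).
#' @return object of class \code{continuous_recording}.
#' @export
continuous_recording <- function(samples, sample_rate, channel_info,
                                 start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  assert_that(is.matrix(samples) && is.numeric(samples), "samples must be a numeric matrix")
  assert_that(nrow(samples) >= 1L, "recording must have at least one channel")
  assert_that(all(is.finite(samples)), "samples must be finite")
  assert_that(is.numeric(sample_rate) && length(sample_rate) == 1L && sample_rate > 0,
              "sample_rate must be a positive scalar")
  channel_info <- as.data.frame(channel_info, stringsAsFactors = FALSE)
  assert_that(all(c("name", "region", "hemisphere") %in% names(channel_info)),
              "channel_info needs columns name, region, hemisphere")
  assert_that(nrow(channel_info) == nrow(samples),
              "channel_info rows must match channel count")
  assert_that(!anyDuplicated(channel_info$name), "channel names must be unique")
  assert_that(all(channel_info$region %in% c("CA1", "PFC", "PPC")),
              "region must be CA1, PFC or PPC")
  assert_that(all(channel_info$hemisphere %in% c("L", "R")),
              "hemisphere must be L or R")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         channel_info = channel_info, start_time = start_time),
    class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              ncol(x$samples) / x$sample_rate))
  cat("  channels:", paste(x$channel_info$name, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a \code{continuous_recording}.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sample_rate

#' Extract one channel by name
#' @param rec a \code{continuous_recording}.
#' @param channel channel name.
#' @return numeric vector of samples.
#' @export
get_channel <- function(rec, channel) {
  i <- match(channel, rec$channel_info$name)
  assert_that(!is.na(i), sprintf("no channel named '%s'", channel))
  rec$samples[i, ]
}

#' Sorted event-time train
#'
#' @param times event times in seconds.
#' @param label free-text label (e.g. "discharge", "spike").
#' @param duration recording extent in seconds; all times must lie in
#'   \code{[0, duration]}.
#' @param warn_unsorted warn (rather than fail) when input times need sorting.
#' @return object of class \code{event_train}.
#' @export
event_train <- function(times, label = "event", duration = NULL,
                        warn_unsorted = TRUE) {
  times <- as.numeric(times)
  assert_that(all(is.finite(times)), "event times must be finite")
  assert_that(all(times >= 0), "event times must be non-negative")
  if (is.unsorted(times)) {
    if (warn_unsorted) warning("event times were unsorted; sorting")
    times <- sort(times)
  }
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  assert_that(length(times) == 0L || max(times) <= duration,
              "event times exceed stated duration")
  structure(list(times = times, label = label, duration = duration),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> '%s': %d events over %.1f s\n",
              x$label, length(x$times), x$duration))
  invisible(x)
}

sidecar_path <- function(path) paste0(sub("\\.[^.\\/]*$", "", path), ".json")

#' Write a recording as flat float32 binary plus a JSON sidecar
#'
#' Samples are stored channel-interleaved (sample 1 of every channel, then
#' sample 2, ...) as little-endian 32-bit floats; sampling rate, channel
#' labels and start time go to a sidecar with the same stem and a
#' \code{.json} extension.
#'
#' @param rec a \code{continuous_recording}.
#' @param path output file path for the binary samples.
#' @param force overwrite an existing file (default FALSE refuses).
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, force = FALSE) {
  assert_that(inherits(rec, "continuous_recording"), "rec must be a continuous_recording")
  assert_that(nrow(rec$samples) >= 1L, "zero-channel recording rejected")
  if (file.exists(path) && !force)
    stop_ictalysis(sprintf("'%s' exists; set force = TRUE to overwrite", path),
                   "overwrite_error")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_ictalysis(
                    sprintf("cannot open '%s' for writing", path), "io_error"))
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  meta <- list(sample_rate = rec$sample_rate,
               start_time = rec$start_time,
               channel_info = rec$channel_info)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by \code{write_recording}
#'
#' @param path path to the flat binary sample file; its JSON sidecar (same
#'   stem, \code{.json}) must exist.
#' @return a \code{continuous_recording}.
#' @export
read_recording <- function(path) {
  assert_that(file.exists(path), sprintf("no such file '%s'", path), "io_error")
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop_ictalysis(sprintf("missing sidecar '%s'", sc), "format_error")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  assert_that(!is.null(meta$sample_rate) && meta$sample_rate > 0,
              "sidecar sample_rate must be positive")
  info <- as.data.frame(meta$channel_info, stringsAsFactors = FALSE)
  n_chan <- nrow(info)
  n_bytes <- file.size(path)
  if (n_bytes %% (4L * n_chan) != 0)
    stop_ictalysis("file size not divisible by 4 x channel count", "corrupt_file_error")
  n_samp <- n_bytes / (4L * n_chan)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n_chan * n_samp, size = 4L, endian = "little")
  continuous_recording(matrix(x, nrow = n_chan), meta$sample_rate, info,
                       start_time = if (is.null(meta$start_time)) 0 else meta$start_time)
}

#' Read an event table from CSV
#'
#' Expects a header \code{time_s,label}. Rows may be filtered to one label.
#' Unsorted times are sorted with a warning; negative times are an error.
#'
#' @param path CSV path.
#' @param label optional label filter; by default all rows are kept and the
#'   train is labelled by the (single) label present, or "event".
#' @param duration recording extent in seconds; if NULL the last event time
#'   is used.
#' @return an \code{event_train}.
#' @export
read_events <- function(path, label = NULL, duration = NULL) {
  assert_that(file.exists(path), sprintf("no such file '%s'", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that("time_s" %in% names(df), "events CSV needs a 'time_s' column", "format_error")
  if (!is.null(label) && "label" %in% names(df)) df <- df[df$label == label, , drop = FALSE]
  lab <- if (!is.null(label)) label
         else if ("label" %in% names(df) && nrow(df) && length(unique(df$label)) == 1L)
           df$label[1L] else "event"
  event_train(df$time_s, label = lab, duration = duration)
}

#' Write an event train to CSV (\code{time_s,label})
#' @param train an \code{event_train}.
#' @param path output CSV path.
#' @export
write_events <- function(train, path) {
  utils::write.csv(data.frame(time_s = train$times, label = train$label),
                   path, row.names = FALSE)
  invisible(path)
}
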