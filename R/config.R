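#' Analysis configuration with published defaults
#'
#' Single declarative container holding every tunable of the pipeline.
#' Defaults are the values used throughout the analyses: 40-Hz order-4
#' high-pass and a 5-SD threshold for discharge detection; 5000-ms segments
#' with 500-ms overlap, time-bandwidth product 3 and 5 tapers for power
#' spectra; 2000-ms segments with 100-ms overlap, TW 5 and 9 tapers for
#' coherence; theta 6-10 Hz, slow-gamma 20-40 Hz, fast-gamma 60-80 Hz bands;
#' autoregressive model order 50 with 1000 frequency points for Granger
#' causality; correlogram windows of 0.5 s (100-ms bins, discharge-discharge)
#' and 1.5 s (200-ms bins, discharge-spike); 10-point trajectory smoothing at
#' 30 fps; 1000 bootstrap iterations.
#'
#' @param ... named overrides of any default listed above.
#' @return object of class \code{analysis_config} (a validated named list).
#' @export
analysis_config <- function(...) {
  cfg <- list(
    # discharge detection
    hp_cutoff = 40, filter_order = 4, threshold = 5,
    merge_gap = 0.05, boundary = 2, min_duration = 0.01,
    extent_smooth = 0.02, rescore = FALSE,
    # preprocessing
    target_rate = 1000, bp_low = 0.1, bp_high = 100,
    # PSD
    psd_segment_ms = 5000, psd_overlap_ms = 500, psd_tw = 3, psd_tapers = 5,
    # coherence
    coh_segment_ms = 2000, coh_overlap_ms = 100, coh_tw = 5, coh_tapers = 9,
    # bands
    bands = list(theta = c(6, 10), slow_gamma = c(20, 40), fast_gamma = c(60, 80)),
    # comodulogram
    pac_phase_range = c(4, 8), pac_amp_range = c(2, 200),
    pac_amp_bw = 4, pac_amp_step = 2, pac_n_bins = 18,
    # Granger
    var_order = 50, n_freqs = 1000,
    # correlograms
    xcorr_id_window = 0.5, xcorr_id_bin = 0.1,
    xcorr_spike_window = 1.5, xcorr_spike_bin = 0.2,
    n_shuffles = 100,
    # locomotion
    fps = 30, smooth_window = 10, px_per_cm = 1,
    # behavior / statistics
    bootstrap_iter = 1000, seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0L,
              paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  pos <- c("hp_cutoff", "filter_order", "threshold", "merge_gap", "boundary",
           "min_duration", "extent_smooth", "target_rate", "bp_high",
           "psd_segment_ms", "psd_tw", "psd_tapers",
           "coh_segment_ms", "coh_tw", "coh_tapers", "pac_amp_bw",
           "pac_amp_step", "pac_n_bins", "var_order", "n_freqs",
           "xcorr_id_window", "xcorr_id_bin", "xcorr_spike_window",
           "xcorr_spike_bin", "fps", "smooth_window", "px_per_cm",
           "bootstrap_iter")
  for (f in pos)
    assert_that(is.numeric(cfg[[f]]) && cfg[[f]] > 0,
                sprintf("config field '%s' must be positive", f))
  for (b in names(cfg$bands)) {
    band <- cfg$bands[[b]]
    assert_that(length(band) == 2L && band[1] < band[2],
                sprintf("band '%s' must have low < high", b))
  }
  assert_that(cfg$pac_phase_range[1] < cfg$pac_phase_range[2] &&
              cfg$pac_amp_range[1] < cfg$pac_amp_range[2],
              "frequency ranges must have low < high")
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v))
      v <- paste(vapply(names(v), function(b)
        sprintf("%s=[%g,%g)", b, v[[b]][1], v[[b]][2]), ""), collapse = " ")
    cat(sprintf("  %-16s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Write a configuration to JSON
#' @param cfg an \code{analysis_config}.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a configuration from JSON
#' @param path JSON path written by \code{write_config}.
#' @return an \code{analysis_config}.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$bands <- lapply(raw$bands, as.numeric)
  do.call(analysis_config, raw)
}
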