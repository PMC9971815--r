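#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline with the instrument
#' defaults: 395 acquisitions per second, a 6.5 um camera pixel behind 44x
#' magnification (0.1477 um sample pixels), 0.5 Hz field stimulation with
#' 2 ms pulses.
#'
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @param pixel_size_um Sample-space pixel pitch. Defaults to
#'   `camera_pixel_um / magnification`. If all three are supplied they must
#'   agree within 1e-4 um.
#' @param camera_pixel_um Physical camera pixel pitch.
#' @param magnification Sample-to-image magnification.
#' @param pacing_hz Electrical stimulation frequency.
#' @param pacing_pulse_ms Stimulus pulse width. Shorter than one frame period
#'   at the default frame rate, so edge times are kept in milliseconds and
#'   snapped to frames (floor convention) only where a frame index is needed.
#' @param block_len_frames Length of the spark-detection intervals over which
#'   baseline and noise statistics are assumed stationary.
#' @param n_blocks Number of such intervals taken from the end of the
#'   recording (the unpaced part).
#' @param smooth_kernel Spatio-temporal smoothing kernel size
#'   (rows, cols, frames) for spark detection; a normalized box.
#' @param k_low,k_high Multipliers of the per-pixel noise SD defining the
#'   lower (event extent) and upper (event seed) detection thresholds
#'   `T_L = mu + k_low * sigma`, `T_H = mu + k_high * sigma`.
#' @param baseline_frames Number of frames at the start of each block used to
#'   re-estimate the baseline F0 in the second detection pass.
#' @param min_area_px,min_duration_frames Spark acceptance filters: minimum
#'   collapsed-footprint area and minimum time above `T_L`.
#' @param connectivity `"face"` (6-neighbourhood in x-y-t, the default) or
#'   `"min_size6"` (26-neighbourhood with components of fewer than 6 voxels
#'   discarded) — the two readings of a minimum 6-pixel connectivity rule.
#' @param dnt_paratubular_max_px Upper DNT bound (pixels) of the paratubular
#'   category; beyond it a pixel or spark counts as detubulated.
#' @param transient_window_s Length of the paced sequence used for transient
#'   analysis (four pacing periods at the defaults).
#' @param crop_frames Window length each transient is cropped to, centred on
#'   its cell-average peak.
#' @param baseline_window_frames Frames immediately before the pacing edge
#'   averaged into the per-pixel baseline map.
#' @param peak_window_frames Frames from the cell-average peak onward
#'   averaged into the per-pixel peak map.
#' @param min_peak_separation_fraction Minimum peak separation for transient
#'   peak finding, as a fraction of one pacing period.
#' @param n_transients Number of consecutive transients analysed.
#' @param channel_scale_ratio Relative magnification of the calcium channel
#'   with respect to the membrane channel introduced by the instrument optics
#'   (0.9 on the reference instrument; 1 for phantoms).
#' @param tubule_filter_um Structuring-element radius of the white top-hat
#'   filter used before tubule thresholding, roughly the width of a stained
#'   tubule in the image (the element must be wider than the structures it
#'   should pass).
#' @param registration_max_shift_px Translation search radius for channel
#'   co-registration.
#' @param registration_min_corr Normalized cross-correlation floor below
#'   which registration falls back to the identity transform with a warning.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$pixel_size_um      # 6.5 / 44 = 0.1477 um
#' frame_period_ms(cfg)   # 1000 / 395 = 2.53 ms
#' @export
analysis_config <- function(frame_rate_hz = 395,
                            pixel_size_um = NULL,
                            camera_pixel_um = 6.5,
                            magnification = 44,
                            pacing_hz = 0.5,
                            pacing_pulse_ms = 2,
                            block_len_frames = 1000,
                            n_blocks = 5,
                            smooth_kernel = c(5, 5, 3),
                            k_low = 2.9,
                            k_high = 5.4,
                            baseline_frames = 100,
                            min_area_px = 50,
                            min_duration_frames = 4,
                            connectivity = c("face", "min_size6"),
                            dnt_paratubular_max_px = 5,
                            transient_window_s = 8,
                            crop_frames = 525,
                            baseline_window_frames = 50,
                            peak_window_frames = 20,
                            min_peak_separation_fraction = 0.95,
                            n_transients = 3,
                            channel_scale_ratio = 0.9,
                            tubule_filter_um = 0.7,
                            registration_max_shift_px = 10,
                            registration_min_corr = 0.1) {
  connectivity <- match.arg(connectivity)
  if (is.null(pixel_size_um)) {
    pixel_size_um <- camera_pixel_um / magnification
  } else if (!is.null(camera_pixel_um) && !is.null(magnification) &&
             abs(pixel_size_um - camera_pixel_um / magnification) > 1e-4) {
    stop("pixel_size_um is inconsistent with camera_pixel_um / magnification")
  }
  cfg <- list(
    frame_rate_hz = frame_rate_hz,
    pixel_size_um = pixel_size_um,
    camera_pixel_um = camera_pixel_um,
    magnification = magnification,
    pacing_hz = pacing_hz,
    pacing_pulse_ms = pacing_pulse_ms,
    block_len_frames = as.integer(block_len_frames),
    n_blocks = as.integer(n_blocks),
    smooth_kernel = as.integer(smooth_kernel),
    k_low = k_low,
    k_high = k_high,
    baseline_frames = as.integer(baseline_frames),
    min_area_px = as.integer(min_area_px),
    min_duration_frames = as.integer(min_duration_frames),
    connectivity = connectivity,
    dnt_paratubular_max_px = dnt_paratubular_max_px,
    transient_window_s = transient_window_s,
    crop_frames = as.integer(crop_frames),
    baseline_window_frames = as.integer(baseline_window_frames),
    peak_window_frames = as.integer(peak_window_frames),
    min_peak_separation_fraction = min_peak_separation_fraction,
    n_transients = as.integer(n_transients),
    channel_scale_ratio = channel_scale_ratio,
    tubule_filter_um = tubule_filter_um,
    registration_max_shift_px = as.integer(registration_max_shift_px),
    registration_min_corr = registration_min_corr
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("frame_rate_hz", "pixel_size_um", "pacing_hz", "pacing_pulse_ms",
           "block_len_frames", "n_blocks", "baseline_frames", "min_area_px",
           "min_duration_frames", "dnt_paratubular_max_px",
           "transient_window_s", "crop_frames", "baseline_window_frames",
           "peak_window_frames", "n_transients", "tubule_filter_um")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single positive number")
    }
  }
  if (length(cfg$smooth_kernel) != 3 || any(cfg$smooth_kernel < 1) ||
      any(cfg$smooth_kernel %% 2 != 1)) {
    stop("smooth_kernel must be three odd positive integers (rows, cols, frames)")
  }
  if (cfg$k_high <= cfg$k_low) stop("k_high must exceed k_low")
  if (cfg$min_peak_separation_fraction <= 0 ||
      cfg$min_peak_separation_fraction > 1) {
    stop("min_peak_separation_fraction must lie in (0, 1]")
  }
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  %g fps, %.4f um/px, pacing %g Hz (%g ms pulses)\n",
              x$frame_rate_hz, x$pixel_size_um, x$pacing_hz, x$pacing_pulse_ms))
  cat(sprintf("  sparks: %d x %d-frame blocks, kernel %s, k = (%.1f, %.1f)\n",
              x$n_blocks, x$block_len_frames,
              paste(x$smooth_kernel, collapse = "x"), x$k_low, x$k_high))
  cat(sprintf("  transients: %d x %d-frame windows, baseline %d / peak %d frames\n",
              x$n_transients, x$crop_frames, x$baseline_window_frames,
              x$peak_window_frames))
  invisible(x)
}

#' Frame period in milliseconds
#' @param config An [analysis_config()].
#' @return Milliseconds per acquired frame.
#' @export
frame_period_ms <- function(config) 1000 / config$frame_rate_hz

#' Convert between pixels and micrometres
#'
#' @param px,um Lengths in pixels / micrometres.
#' @param config An [analysis_config()] supplying the pixel pitch.
#' @return The converted length.
#' @export
px_to_um <- function(px, config) px * config$pixel_size_um

#' @rdname px_to_um
#' @export
um_to_px <- function(um, config) um / config$pixel_size_um

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}
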