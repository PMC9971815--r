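#' Construct a time-lapse stack
#'
#' The basic container for one spectral channel of an x-y-t recording:
#' a rows x cols x frames array of non-negative intensities (detector digital
#' numbers, processed as floating point) plus the acquisition geometry.
#'
#' @param intensities rows x cols x frames numeric array (a matrix is treated
#'   as a single frame).
#' @param channel `"calcium"` or `"membrane"`.
#' @param frame_rate_hz Acquisition rate.
#' @param pixel_size_um Sample-space pixel pitch.
#' @param origin_frame_index Index of the first frame relative to the full
#'   acquisition (1 for an uncropped recording).
#' @return A `timelapse_stack`.
#' @export
timelapse_stack <- function(intensities, channel = c("calcium", "membrane"),
                            frame_rate_hz = 395, pixel_size_um = 6.5 / 44,
                            origin_frame_index = 1L) {
  channel <- match.arg(channel)
  if (is.matrix(intensities)) {
    intensities <- array(intensities, c(dim(intensities), 1L))
  }
  stopifnot(length(dim(intensities)) == 3, dim(intensities)[3] >= 1)
  if (any(intensities < 0)) stop("stack intensities must be non-negative")
  structure(
    list(intensities = intensities, channel = channel,
         frame_rate_hz = frame_rate_hz, pixel_size_um = pixel_size_um,
         origin_frame_index = as.integer(origin_frame_index)),
    class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<timelapse_stack> %s: %d x %d px, %d frames @ %g fps (%.4f um/px)\n",
              x$channel, d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

n_frames <- function(stack) dim(stack$intensities)[3]

#' Temporal mean image of a stack
#' @param stack A [timelapse_stack()].
#' @return A rows x cols matrix.
#' @export
temporal_mean <- function(stack) {
  d <- dim(stack$intensities)
  matrix(rowMeans(matrix(stack$intensities, d[1] * d[2], d[3])), d[1], d[2])
}

#' Construct a pacing trace and detect stimulus edges
#'
#' The synchronization monitor signal of the field-stimulation unit: a
#' top-hat pulse train sampled at its own (typically higher) rate. Rising
#' edges are detected at the half-amplitude level crossing and kept in
#' milliseconds; they are snapped to frame indices (floor convention) only by
#' the operations that need one.
#'
#' @param time_ms Sample times in ms.
#' @param level Signal level per sample.
#' @param tolerance Allowed relative deviation of consecutive edge spacings
#'   from their median before an error is raised.
#' @return A `pacing_trace` with `edge_times_ms` and `period_ms`
#'   (`NA` when fewer than two edges are present).
#' @export
pacing_trace <- function(time_ms, level, tolerance = 0.05) {
  stopifnot(length(time_ms) == length(level), !is.unsorted(time_ms))
  lo <- min(level); hi <- max(level)
  edges <- numeric(0)
  if (hi > lo) {
    thr <- (hi + lo) / 2
    up <- which(level[-1] > thr & level[-length(level)] <= thr)
    edges <- time_ms[up + 1L]
  }
  period <- NA_real_
  if (length(edges) >= 2) {
    gaps <- diff(edges)
    period <- stats::median(gaps)
    if (any(abs(gaps - period) > tolerance * period)) {
      stop("pacing edges are not evenly spaced (", tolerance * 100,
           "% tolerance); check the synchronization trace")
    }
  }
  structure(list(time_ms = time_ms, level = level,
                 edge_times_ms = edges, period_ms = period),
            class = "pacing_trace")
}

#' @export
print.pacing_trace <- function(x, ...) {
  cat(sprintf("<pacing_trace> %d samples, %d rising edges",
              length(x$time_ms), length(x$edge_times_ms)))
  if (!is.na(x$period_ms)) cat(sprintf(", period %.1f ms", x$period_ms))
  cat("\n")
  invisible(x)
}

#' Read a pacing trace from CSV
#'
#' Expects columns `time_ms` and `level`.
#' @param path CSV file path.
#' @inheritParams pacing_trace
#' @return A [pacing_trace()].
#' @export
read_pacing_csv <- function(path, tolerance = 0.05) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "level") %in% names(df))) {
    stop("pacing CSV must have columns time_ms and level")
  }
  pacing_trace(df$time_ms, df$level, tolerance = tolerance)
}

#' Read a multi-frame TIFF as a time-lapse stack
#'
#' Integer TIFFs are read at their native digital-number scale; float TIFFs
#' are read as stored. TIFF is the supported interchange format for
#' recordings.
#'
#' @param path TIFF file path.
#' @inheritParams timelapse_stack
#' @return A [timelapse_stack()].
#' @export
read_tiff_stack <- function(path, channel = "calcium", frame_rate_hz = 395,
                            pixel_size_um = 6.5 / 44, origin_frame_index = 1L) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  timelapse_stack(arr, channel = channel, frame_rate_hz = frame_rate_hz,
                  pixel_size_um = pixel_size_um,
                  origin_frame_index = origin_frame_index)
}

#' Write a stack (or single map) to TIFF
#'
#' Integer data are written as 16-bit samples and round-trip exactly;
#' with `float = TRUE` values must already lie in `[0, 1]` and are written as
#' 32-bit samples (relative precision 2^-32).
#'
#' @param x A [timelapse_stack()], 3D array or matrix.
#' @param path Output file.
#' @param float Write 32-bit float samples instead of 16-bit integers.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path, float = FALSE) {
  arr <- if (inherits(x, "timelapse_stack")) x$intensities else x
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  frames <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  if (float) {
    if (min(arr) < 0 || max(arr) > 1) {
      stop("32-bit TIFF output requires values in [0, 1]")
    }
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  } else {
    if (any(arr != round(arr)) || max(arr) > 65535) {
      stop("integer TIFF output requires integer data in [0, 65535]")
    }
    frames <- lapply(frames, function(f) f / 65535)
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Bundle the two channels, pacing trace and metadata of one recording
#'
#' @param calcium,membrane [timelapse_stack()]s with identical frame counts.
#' @param pacing A [pacing_trace()], or `NULL` for an unpaced bundle (spark
#'   analysis only; transient stages refuse to run).
#' @param metadata Named list carried through to result tables. Ventricle
#'   labels stay opaque strings (blinded "A"/"B"); unblinding is a metadata
#'   join downstream, not pipeline logic.
#' @return A `recording_bundle`.
#' @export
recording_bundle <- function(calcium, membrane, pacing = NULL,
                             metadata = list()) {
  stopifnot(inherits(calcium, "timelapse_stack"),
            inherits(membrane, "timelapse_stack"))
  if (n_frames(calcium) != n_frames(membrane)) {
    stop("calcium and membrane stacks have different frame counts")
  }
  unpaced <- is.null(pacing) || length(pacing$edge_times_ms) == 0
  structure(list(calcium = calcium, membrane = membrane, pacing = pacing,
                 metadata = metadata, unpaced = unpaced),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> %d frames, %s\n", n_frames(x$calcium),
              if (x$unpaced) "unpaced" else
                sprintf("%d pacing edges", length(x$pacing$edge_times_ms))))
  invisible(x)
}

#' Read a dual-channel recording from disk
#'
#' @param calcium_path,membrane_path Multi-frame TIFFs of the two channels,
#'   equal frame counts.
#' @param pacing_path CSV pacing trace (`time_ms`, `level`), or `NULL`. A
#'   trace without any pulse yields an unpaced bundle.
#' @param config An [analysis_config()].
#' @param metadata Passed to [recording_bundle()].
#' @return A [recording_bundle()].
#' @export
read_recording <- function(calcium_path, membrane_path, pacing_path = NULL,
                           config = analysis_config(), metadata = list()) {
  calcium <- read_tiff_stack(calcium_path, "calcium",
                             config$frame_rate_hz, config$pixel_size_um)
  membrane <- read_tiff_stack(membrane_path, "membrane",
                              config$frame_rate_hz, config$pixel_size_um)
  pacing <- if (!is.null(pacing_path)) read_pacing_csv(pacing_path)
  recording_bundle(calcium, membrane, pacing, metadata)
}

#' Read nucleus outlines from a polygon file
#'
#' Supports a GeoJSON-like JSON list (`[{"x": [...], "y": [...]}, ...]`) or a
#' CSV with columns `roi`, `x`, `y`. Coordinates are pixel positions: `x` is
#' the column, `y` the row, pixel centres at integers (1-based).
#'
#' @param path Polygon file (`.json` or `.csv`).
#' @return A list of polygons, each a list with `x` and `y` vectors.
#' @export
read_nuclei_polygons <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    polys <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("roi", "x", "y") %in% names(df))) {
      stop("polygon CSV must have columns roi, x, y")
    }
    polys <- lapply(split(df, df$roi), function(p) list(x = p$x, y = p$y))
    names(polys) <- NULL
  }
  for (p in polys) {
    if (is.null(p$x) || is.null(p$y) || length(p$x) != length(p$y) ||
        length(p$x) < 3) {
      stop("each polygon needs matched x/y vectors with at least 3 vertices")
    }
  }
  polys
}

#' Read a T50 map written by [write_results()]
#'
#' @param path A `t50_mean.tif` / `t50_sd.tif` file.
#' @return Matrix of milliseconds with `NA` at undefined pixels.
#' @export
read_t50_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  m <- m * 1000
  m[m == 0] <- NA_real_
  m
}

# Documented spark-table schema (one row per accepted spark).
spark_table_columns <- c(
  "id", "block", "t_on_frames", "area_px", "area_um2", "com_x_px", "com_y_px",
  "amplitude", "fdhm_ms", "fwhm_x_um", "fwhm_y_um", "mass_ms_um",
  "dnt_px", "category", "flags")

empty_spark_table <- function() {
  df <- data.frame(id = integer(0), block = integer(0), t_on_frames = integer(0),
                   area_px = integer(0), area_um2 = numeric(0),
                   com_x_px = numeric(0), com_y_px = numeric(0),
                   amplitude = numeric(0), fdhm_ms = numeric(0),
                   fwhm_x_um = numeric(0), fwhm_y_um = numeric(0),
                   mass_ms_um = numeric(0), dnt_px = numeric(0),
                   category = character(0), flags = character(0))
  df
}

#' Write pipeline results to a directory
#'
#' Emits `sparks.csv` (one row per spark, schema in the spark-table
#' documentation; an empty spark list produces a header-only table),
#' `t50_mean.tif` / `t50_sd.tif` (32-bit samples holding milliseconds / 1000,
#' sentinel 0 for pixels outside the valid mask — use [read_t50_tiff()] to
#' recover milliseconds), `t50_regions.csv` and, when present,
#' `t50_dnt_fit.csv`.
#'
#' @param sparks Spark table from [detect_sparks()] (may have zero rows).
#' @param t50 A `t50_map` from [aggregate_t50_maps()], or `NULL`.
#' @param regions A `regional_t50_summary` from [summarize_regions()], or
#'   `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param fit A `t50_dnt_fit` from [fit_t50_vs_dnt()], or `NULL`.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(sparks, t50 = NULL, regions = NULL, out_dir,
                          fit = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  sp <- if (is.null(sparks) || nrow(sparks) == 0) empty_spark_table() else
    sparks[, spark_table_columns]
  f <- file.path(out_dir, "sparks.csv")
  utils::write.csv(sp, f, row.names = FALSE)
  written <- c(written, f)
  if (!is.null(t50)) {
    for (layer in c("mean", "sd")) {
      m <- t50[[layer]] / 1000
      m[!t50$valid | !is.finite(m)] <- 0
      f <- file.path(out_dir, sprintf("t50_%s.tif", layer))
      write_tiff_stack(m, f, float = TRUE)
      written <- c(written, f)
    }
  }
  if (!is.null(regions)) {
    f <- file.path(out_dir, "t50_regions.csv")
    utils::write.csv(as.data.frame(unclass(regions)[!vapply(unclass(regions), is.null, TRUE)]),
                     f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(fit)) {
    f <- file.path(out_dir, "t50_dnt_fit.csv")
    utils::write.csv(as.data.frame(fit), f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
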