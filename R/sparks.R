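#' Prepare the unpaced segment for spark detection
#'
#' Takes the last `n_blocks * block_len_frames` frames of the recording (the
#' part acquired with stimulation switched off), applies normalized box
#' smoothing with the configured spatio-temporal kernel, tiles the segment
#' into disjoint blocks over which the baseline is assumed stationary, and
#' normalizes each block by its per-pixel temporal mean. Per-pixel mean and
#' SD of dF/F0 per block give the detection thresholds
#' `T_L = mu + k_low * sigma` and `T_H = mu + k_high * sigma`.
#'
#' Pixels with zero noise (possible in noiseless synthetic data) are given an
#' SD floor of machine epsilon and excluded from seeding events.
#'
#' @param calcium A background-subtracted [timelapse_stack()].
#' @param cell A [cell_mask()]; detection is restricted to cell pixels.
#' @param config An [analysis_config()].
#' @return A `spark_segment` holding the smoothed segment (as an
#'   npx x frames matrix), per-block first-pass baseline maps `f0` and the
#'   threshold statistics `mu` and `sigma` (npx x n_blocks).
#' @export
prepare_spark_segment <- function(calcium, cell, config = analysis_config()) {
  nb <- config$n_blocks
  bl <- config$block_len_frames
  need <- nb * bl
  nt <- n_frames(calcium)
  if (nt < need) {
    stop(sprintf("segment of %d frames is shorter than %d blocks of %d frames",
                 nt, nb, bl))
  }
  first <- nt - need + 1L
  d <- dim(calcium$intensities)
  smoothed <- box_smooth_3d(calcium$intensities[, , first:nt, drop = FALSE],
                            config$smooth_kernel)
  npx <- d[1] * d[2]
  dim(smoothed) <- c(npx, need)
  valid <- as.vector(cell$mask)
  f0 <- matrix(NA_real_, npx, nb)
  mu <- matrix(0, npx, nb)
  sigma <- matrix(0, npx, nb)
  for (b in seq_len(nb)) {
    fr <- ((b - 1L) * bl + 1L):(b * bl)
    f0[, b] <- rowMeans(smoothed[, fr, drop = FALSE])
    ok <- valid & f0[, b] > 0
    dff <- smoothed[ok, fr, drop = FALSE] / f0[ok, b] - 1
    mu[ok, b] <- rowMeans(dff)
    sigma[ok, b] <- sqrt(pmax(0, rowMeans(dff^2) - mu[ok, b]^2))
  }
  structure(list(
    smoothed = smoothed, f0 = f0, mu = mu, sigma = sigma,
    valid = matrix(valid, d[1], d[2]),
    dims = c(d[1], d[2], need), n_blocks = nb, block_len = bl,
    origin_frame = calcium$origin_frame_index + first - 1L,
    frame_rate_hz = calcium$frame_rate_hz,
    pixel_size_um = calcium$pixel_size_um, config = config),
    class = "spark_segment")
}

#' @export
print.spark_segment <- function(x, ...) {
  cat(sprintf("<spark_segment> %d x %d px, %d blocks x %d frames\n",
              x$dims[1], x$dims[2], x$n_blocks, x$block_len))
  invisible(x)
}

#' Normalized dF/F0 of one detection block
#'
#' `smoothed / F0 - 1` for block `b` under the given per-block baseline
#' maps; zero where the baseline is non-positive or outside the cell.
#'
#' @param seg A [prepare_spark_segment()] result.
#' @param b Block index.
#' @param f0 Baseline maps (npx x n_blocks); defaults to the first-pass
#'   block means.
#' @return An npx x block_len matrix.
#' @export
block_dff <- function(seg, b, f0 = seg$f0) {
  fr <- ((b - 1L) * seg$block_len + 1L):(b * seg$block_len)
  out <- matrix(0, nrow(seg$smoothed), seg$block_len)
  ok <- as.vector(seg$valid) & f0[, b] > 0
  out[ok, ] <- seg$smoothed[ok, fr, drop = FALSE] / f0[ok, b] - 1
  out
}

# One hysteresis detection pass over one block. Returns a list of voxel-index
# vectors (linear indices into the d1 x d2 x block_len block array).
.detect_block <- function(seg, dff_b, mu_b, sigma_b, config) {
  d <- seg$dims
  npx <- d[1] * d[2]
  eps <- .Machine$double.eps
  sig <- pmax(sigma_b, eps)
  seed_ok <- sigma_b > eps & as.vector(seg$valid)
  tl <- mu_b + config$k_low * sig
  th <- mu_b + config$k_high * sig
  above_l <- dff_b > tl & as.vector(seg$valid)
  idx <- which(above_l)
  if (!length(idx)) return(list())
  conn <- if (config$connectivity == "face") "face" else "full"
  memb <- label_components_3d(idx, c(d[1], d[2], seg$block_len), conn)
  pxi <- ((idx - 1L) %% npx) + 1L
  is_seed <- dff_b[idx] > th[pxi] & seed_ok[pxi]
  keep <- unique(memb[is_seed])
  if (config$connectivity == "min_size6") {
    counts <- tabulate(memb)
    keep <- keep[counts[keep] >= 6L]
  }
  lapply(keep, function(k) idx[memb == k])
}

#' Detect spark candidates with the two-pass thresholding algorithm
#'
#' Pass 1 detects preliminary events on the block-mean-normalized data. The
#' voxels of those events are then masked out and the baseline `F0`
#' recalculated over the first `baseline_frames` of each block (block mean
#' over unmasked frames as fallback for pixels whose baseline window is
#' entirely masked); per-pixel mean and SD are likewise recomputed with
#' event voxels excluded, and the detection is repeated. Events are
#' connected components in x-y-t (face-adjacent by default) above `T_L`
#' containing at least one voxel above `T_H`.
#'
#' @param seg A [prepare_spark_segment()] result.
#' @return List with `components` (final pass; each a
#'   `list(block, voxels)`), `f0_2`, `mu2`, `sigma2` (second-pass maps) and
#'   `preliminary` (first-pass components).
#' @export
detect_spark_candidates <- function(seg) {
  config <- seg$config
  d <- seg$dims
  npx <- d[1] * d[2]
  bl <- seg$block_len
  valid <- as.vector(seg$valid)
  nbf <- min(config$baseline_frames, bl)
  f0_2 <- seg$f0
  mu2 <- matrix(0, npx, seg$n_blocks)
  sigma2 <- matrix(0, npx, seg$n_blocks)
  prelim <- list()
  final <- list()
  for (b in seq_len(seg$n_blocks)) {
    dff_b <- block_dff(seg, b)
    comps1 <- .detect_block(seg, dff_b, seg$mu[, b], seg$sigma[, b], config)
    for (v in comps1) {
      prelim[[length(prelim) + 1L]] <- list(block = b, voxels = v)
    }
    # mask pass-1 voxels, recompute F0 and moments
    w <- matrix(TRUE, npx, bl)
    for (v in comps1) w[v] <- FALSE
    fr <- ((b - 1L) * bl + 1L):(b * bl)
    sm_b <- seg$smoothed[, fr, drop = FALSE]
    n_base <- rowSums(w[, seq_len(nbf), drop = FALSE])
    s_base <- rowSums(sm_b[, seq_len(nbf), drop = FALSE] *
                        w[, seq_len(nbf), drop = FALSE])
    n_all <- rowSums(w)
    s_all <- rowSums(sm_b * w)
    f0_2[, b] <- ifelse(n_base > 0, s_base / n_base,
                        ifelse(n_all > 0, s_all / n_all, seg$f0[, b]))
    dff_b2 <- block_dff(seg, b, f0_2)
    sums <- rowSums(dff_b2 * w)
    sq <- rowSums(dff_b2^2 * w)
    has <- valid & f0_2[, b] > 0 & n_all > 0
    mu2[has, b] <- sums[has] / n_all[has]
    sigma2[has, b] <- sqrt(pmax(0, sq[has] / n_all[has] - mu2[has, b]^2))
    comps2 <- .detect_block(seg, dff_b2, mu2[, b], sigma2[, b], config)
    for (v in comps2) {
      final[[length(final) + 1L]] <- list(block = b, voxels = v)
    }
  }
  list(components = final, f0_2 = f0_2, mu2 = mu2, sigma2 = sigma2,
       preliminary = prelim)
}

#' Characterize one detected spark
#'
#' Collapses the x-y-t component along time to a 2D footprint, averages the
#' normalized intensity over that footprint per frame to get the temporal
#' profile, and derives: amplitude (peak minus baseline over baseline of the
#' profile, the baseline taken over the block frames outside the event),
#' FDHM (time between the first and last profile points at or above F50,
#' the level halfway between baseline and peak), centre of mass
#' (intensity-weighted over the component), FWHM in x and y (contiguous run
#' of pixels at or above F50 along the row/column lines through the COM at
#' the peak frame, times the pixel size) and spark mass
#' `amplitude x mean(FWHM_x, FWHM_y) x FDHM`.
#'
#' Events whose profile never falls back below F50 within the block are
#' flagged `unfinished`; events touching a block time-boundary are flagged
#' `boundary_truncated`. Both are excluded by [filter_sparks()].
#'
#' @param component A `list(block, voxels)` from [detect_spark_candidates()].
#' @param seg The [prepare_spark_segment()] result.
#' @param dff_b The component block's second-pass dF/F0 matrix from
#'   [block_dff()].
#' @param id Integer id assigned to the event.
#' @return One-row data.frame in the spark-table schema (plus `peak_frame`,
#'   the segment-wide frame of the profile peak).
#' @export
characterize_spark <- function(component, seg, dff_b, id = 1L) {
  d <- seg$dims
  npx <- d[1] * d[2]
  bl <- seg$block_len
  v <- component$voxels
  px <- ((v - 1L) %% npx) + 1L
  tt <- ((v - 1L) %/% npx) + 1L   # frame within block
  vals <- dff_b[cbind(px, tt)]

  foot <- unique(px)
  area_px <- length(foot)
  t_min <- min(tt); t_max <- max(tt)
  t_on <- t_max - t_min + 1L

  profile <- colMeans(dff_b[foot, , drop = FALSE]) + 1  # normalized F/F0
  off_frames <- setdiff(seq_len(bl), t_min:t_max)
  baseline <- if (length(off_frames)) mean(profile[off_frames]) else 1
  pk_rel <- which.max(profile[t_min:t_max])
  peak_frame <- t_min + pk_rel - 1L
  peak <- profile[peak_frame]
  amplitude <- (peak - baseline) / baseline
  f50 <- baseline + (peak - baseline) / 2

  # FDHM: contiguous run around the peak at or above F50
  first_above <- peak_frame
  while (first_above > 1L && profile[first_above - 1L] >= f50) {
    first_above <- first_above - 1L
  }
  last_above <- peak_frame
  while (last_above < bl && profile[last_above + 1L] >= f50) {
    last_above <- last_above + 1L
  }
  unfinished <- last_above == bl && profile[bl] >= f50
  boundary <- t_min == 1L || t_max == bl
  fdhm_ms <- (last_above - first_above) * 1000 / seg$frame_rate_hz

  # centre of mass from the component's intensity-weighted projections
  ar_r <- ((px - 1L) %% d[1]) + 1L
  ar_c <- ((px - 1L) %/% d[1]) + 1L
  com_row <- sum(ar_r * vals) / sum(vals)
  com_col <- sum(ar_c * vals) / sum(vals)

  # FWHM from line profiles through (peak frame, COM)
  r0 <- min(max(round(com_row), 1L), d[1])
  c0 <- min(max(round(com_col), 1L), d[2])
  peak_img <- matrix(dff_b[, peak_frame], d[1], d[2]) + 1
  fwhm_x_px <- .halfmax_run(peak_img[r0, ], c0, f50)
  fwhm_y_px <- .halfmax_run(peak_img[, c0], r0, f50)
  fwhm_x_um <- fwhm_x_px * seg$pixel_size_um
  fwhm_y_um <- fwhm_y_px * seg$pixel_size_um
  fwhm_mean_um <- (fwhm_x_um + fwhm_y_um) / 2
  mass <- amplitude * fwhm_mean_um * fdhm_ms

  flags <- paste(c(if (unfinished) "unfinished",
                   if (boundary) "boundary_truncated"), collapse = ",")
  data.frame(
    id = as.integer(id), block = component$block, t_on_frames = t_on,
    area_px = area_px, area_um2 = area_px * seg$pixel_size_um^2,
    com_x_px = com_col, com_y_px = com_row,
    amplitude = amplitude, fdhm_ms = fdhm_ms,
    fwhm_x_um = fwhm_x_um, fwhm_y_um = fwhm_y_um,
    mass_ms_um = mass, dnt_px = NA_real_, category = NA_character_,
    flags = flags, peak_frame = peak_frame + (component$block - 1L) * bl,
    stringsAsFactors = FALSE)
}

# Length of the contiguous run of values >= level through position `at`.
.halfmax_run <- function(line, at, level) {
  if (line[at] < level) return(0L)
  lo <- at
  while (lo > 1L && line[lo - 1L] >= level) lo <- lo - 1L
  hi <- at
  while (hi < length(line) && line[hi + 1L] >= level) hi <- hi + 1L
  hi - lo + 1L
}

#' Filter characterized sparks
#'
#' Retains events with a collapsed-footprint area of at least
#' `min_area_px` (inclusive: "below 50 px" is rejected), an on-time of at
#' least `min_duration_frames` above the lower threshold, and no
#' `unfinished` or `boundary_truncated` flag.
#'
#' @param events Spark data.frame (rows from [characterize_spark()]).
#' @param config An [analysis_config()].
#' @return The retained subset.
#' @export
filter_sparks <- function(events, config = analysis_config()) {
  if (is.null(events) || nrow(events) == 0) return(events)
  keep <- events$area_px >= config$min_area_px &
    events$t_on_frames >= config$min_duration_frames &
    events$flags == ""
  events[keep, , drop = FALSE]
}

#' Attach DNT values and categories to sparks
#'
#' Looks up the DNT map at each spark's rounded centre of mass.
#'
#' @param sparks Spark data.frame.
#' @param dnt A `dnt_map` from [compute_dnt_map()].
#' @return `sparks` with `dnt_px` and `category` filled in.
#' @export
assign_spark_dnt <- function(sparks, dnt) {
  if (nrow(sparks) == 0) return(sparks)
  r <- pmin(pmax(round(sparks$com_y_px), 1L), nrow(dnt$dnt_px))
  c <- pmin(pmax(round(sparks$com_x_px), 1L), ncol(dnt$dnt_px))
  sparks$dnt_px <- dnt$dnt_px[cbind(r, c)]
  sparks$category <- dnt_category(sparks$dnt_px, dnt$paratubular_max_px)
  sparks
}

#' Detect and characterize calcium sparks
#'
#' End-to-end spark stage: prepares the unpaced segment, runs the two-pass
#' hysteresis detection, characterizes every component, applies the
#' area/duration/unfinished filters and, when a DNT map is given, attaches
#' tubule-distance categories.
#'
#' @param calcium Background-subtracted calcium [timelapse_stack()].
#' @param cell A [cell_mask()].
#' @param dnt Optional `dnt_map`.
#' @param config An [analysis_config()].
#' @return Spark table (data.frame, one row per accepted spark) with the
#'   detection segment duration attached as attribute
#'   `"segment_duration_s"` and the raw candidate count as
#'   `"n_candidates"`.
#' @export
detect_sparks <- function(calcium, cell, dnt = NULL,
                          config = analysis_config()) {
  seg <- prepare_spark_segment(calcium, cell, config)
  det <- detect_spark_candidates(seg)
  events <- empty_spark_table()
  events$peak_frame <- integer(0)
  if (length(det$components)) {
    blocks <- vapply(det$components, function(cp) cp$block, integer(1))
    rows <- list()
    for (b in unique(blocks)) {
      dff_b <- block_dff(seg, b, det$f0_2)
      for (i in which(blocks == b)) {
        rows[[length(rows) + 1L]] <-
          characterize_spark(det$components[[i]], seg, dff_b, id = i)
      }
    }
    events <- do.call(rbind, rows)
  }
  final <- filter_sparks(events, config)
  if (nrow(final)) final$id <- seq_len(nrow(final))
  if (!is.null(dnt)) final <- assign_spark_dnt(final, dnt)
  attr(final, "segment_duration_s") <-
    seg$n_blocks * seg$block_len / seg$frame_rate_hz
  attr(final, "n_candidates") <- length(det$components)
  final
}

#' DNT-resolved spark rates
#'
#' Spark rate per DNT category, expressed as sparks per 100 um^2 of category
#' area per second, together with the fraction of sparks per category.
#' Categories with zero area get `NA` (undefined), not 0.
#'
#' @param sparks Spark table with `category` filled in.
#' @param dnt A `dnt_map`.
#' @param cell A [cell_mask()].
#' @param duration_s Analyzed recording duration in seconds.
#' @param config An [analysis_config()].
#' @return data.frame with one row per category: `n_sparks`, `area_um2`,
#'   `duration_s`, `rate_per_100um2_s`, `fraction`.
#' @export
compute_spark_rates <- function(sparks, dnt, cell, duration_s,
                                config = analysis_config()) {
  stopifnot(duration_s > 0)
  cats <- c("epitubular", "paratubular", "detubulated")
  area_um2 <- vapply(cats, function(k) {
    sum(dnt$category == k, na.rm = TRUE) * cell$pixel_size_um^2
  }, numeric(1))
  n <- vapply(cats, function(k) sum(sparks$category == k, na.rm = TRUE),
              numeric(1))
  rate <- ifelse(area_um2 > 0, n / (area_um2 / 100) / duration_s, NA_real_)
  total <- sum(n)
  data.frame(category = cats, n_sparks = as.integer(n), area_um2 = area_um2,
             duration_s = duration_s, rate_per_100um2_s = rate,
             fraction = if (total > 0) n / total else rep(NA_real_, 3),
             row.names = NULL, stringsAsFactors = FALSE)
}
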