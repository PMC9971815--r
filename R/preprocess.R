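#' Cell footprint mask
#'
#' @param mask rows x cols logical matrix; must contain a single connected
#'   foreground component.
#' @param pixel_size_um Pixel pitch used to derive the area in um^2.
#' @return A `cell_mask` with `area_px` and `area_um2`.
#' @export
cell_mask <- function(mask, pixel_size_um = 6.5 / 44) {
  stopifnot(is.matrix(mask), is.logical(mask))
  area <- sum(mask)
  if (area == 0) stop("no cell found: empty mask")
  structure(list(mask = mask, area_px = area,
                 area_um2 = area * pixel_size_um^2,
                 pixel_size_um = pixel_size_um),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d px (%.1f um2) in a %d x %d frame\n",
              x$area_px, x$area_um2, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Co-register the two spectral channels
#'
#' The instrument optics magnify the calcium channel by `scale_ratio`
#' relative to the membrane channel, and the two half-sensor fields of view
#' are never perfectly aligned. The membrane channel is rescaled onto the
#' calcium pixel grid (bilinear, about the frame centre) and then translated
#' by the integer shift that maximizes the normalized cross-correlation of
#' the two temporal-mean images. The calcium channel — the quantitative
#' channel — is never resampled, preserving dF/F0 fidelity.
#'
#' @param calcium,membrane [timelapse_stack()]s with equal frame counts.
#' @param scale_ratio Magnification of the calcium channel relative to the
#'   membrane channel (default from `config`; 1 for phantoms rendered on a
#'   common grid).
#' @param config An [analysis_config()] supplying the search radius and the
#'   correlation floor below which a warning is issued and the identity
#'   translation used.
#' @return List with the untouched `calcium` stack, the registered
#'   `membrane` stack, the applied integer `shift` (rows, cols) and the
#'   peak normalized cross-correlation `correlation`.
#' @export
coregister_channels <- function(calcium, membrane,
                                scale_ratio = NULL,
                                config = analysis_config()) {
  if (n_frames(calcium) != n_frames(membrane)) {
    stop("stacks must have equal frame counts")
  }
  if (is.null(scale_ratio)) scale_ratio <- config$channel_scale_ratio
  stopifnot(scale_ratio > 0)
  mem <- membrane$intensities
  if (scale_ratio != 1) {
    for (t in seq_len(dim(mem)[3])) {
      mem[, , t] <- rescale_about_center(mem[, , t], scale_ratio)
    }
  }
  ref <- temporal_mean(calcium)
  mov_stack <- membrane
  mov_stack$intensities <- mem
  mov <- temporal_mean(mov_stack)
  best <- .best_translation(ref, mov, config$registration_max_shift_px)
  if (best$corr < config$registration_min_corr) {
    warning(sprintf(
      "registration correlation %.3f below floor %.3f; using identity transform",
      best$corr, config$registration_min_corr))
    best$shift <- c(0L, 0L)
  }
  if (any(best$shift != 0L)) {
    for (t in seq_len(dim(mem)[3])) {
      mem[, , t] <- shift_matrix(mem[, , t], best$shift)
    }
  }
  mov_stack$intensities <- mem
  list(calcium = calcium, membrane = mov_stack,
       shift = best$shift, correlation = best$corr)
}

# Integer translation (rows, cols) of `mov` maximizing NCC against `ref`,
# searched exhaustively within +/- max_shift.
.best_translation <- function(ref, mov, max_shift) {
  shifts <- -max_shift:max_shift
  best <- list(shift = c(0L, 0L), corr = -Inf)
  nr <- nrow(ref); nc <- ncol(ref)
  for (sr in shifts) {
    r_ref <- max(1, 1 + sr):min(nr, nr + sr)
    r_mov <- r_ref - sr
    for (sc in shifts) {
      c_ref <- max(1, 1 + sc):min(nc, nc + sc)
      c_mov <- c_ref - sc
      a <- ref[r_ref, c_ref]
      b <- mov[r_mov, c_mov]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      cc <- stats::cor(as.numeric(a), as.numeric(b))
      if (cc > best$corr) best <- list(shift = c(sr, sc), corr = cc)
    }
  }
  best
}

#' Subtract the background from a stack
#'
#' Estimates a per-frame scalar background as the median intensity outside a
#' dilated provisional cell region (Otsu on the temporal mean) and subtracts
#' it, clipping at zero. When a frame has no extracellular pixels the global
#' lowest-percentile intensity is used instead.
#'
#' @param stack A [timelapse_stack()].
#' @param cell_mask_hint Optional [cell_mask()] marking the cell; when absent
#'   a provisional mask is derived from the stack itself.
#' @param dilate_um How far the provisional cell region is dilated before
#'   sampling the background.
#' @param fallback_percentile Percentile used when a frame is entirely
#'   foreground.
#' @return The background-subtracted stack; per-frame estimates in
#'   `attr(, "background_dn")`.
#' @export
subtract_background <- function(stack, cell_mask_hint = NULL,
                                dilate_um = 1, fallback_percentile = 0.01) {
  arr <- stack$intensities
  d <- dim(arr)
  mask <- if (!is.null(cell_mask_hint)) cell_mask_hint$mask else {
    mean_img <- temporal_mean(stack)
    if (max(mean_img) > min(mean_img)) {
      mean_img > otsu_threshold(mean_img)
    } else {
      matrix(FALSE, d[1], d[2])
    }
  }
  rad <- um_to_px(dilate_um, list(pixel_size_um = stack$pixel_size_um))
  if (any(mask)) {
    mask <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(mask * 1), disc_kernel(rad))) > 0
  }
  outside <- which(!mask)
  flat <- matrix(arr, d[1] * d[2], d[3])
  bg <- if (length(outside)) {
    apply(flat[outside, , drop = FALSE], 2, stats::median)
  } else {
    rep(stats::quantile(arr, fallback_percentile, names = FALSE), d[3])
  }
  flat <- sweep(flat, 2, bg)
  flat[flat < 0] <- 0
  out <- stack
  out$intensities <- array(flat, d)
  attr(out, "background_dn") <- bg
  out
}

#' Segment the cell footprint
#'
#' Otsu threshold on the temporal-mean calcium image, morphological closing
#' (disc of ~0.5 um radius), hole filling, and retention of the largest
#' connected component. Invariant to global intensity scaling of the input.
#'
#' @param calcium A [timelapse_stack()] (typically background-subtracted).
#' @param closing_um Radius of the closing disc.
#' @return A [cell_mask()].
#' @export
segment_cell <- function(calcium, closing_um = 0.5) {
  mean_img <- temporal_mean(calcium)
  if (max(mean_img) == min(mean_img)) stop("no cell found: uniform image")
  m <- mean_img > otsu_threshold(mean_img)
  if (!any(m)) stop("no cell found: empty mask")
  rad <- um_to_px(closing_um, list(pixel_size_um = calcium$pixel_size_um))
  img <- EBImage::closing(EBImage::Image(m * 1), disc_kernel(rad))
  img <- EBImage::fillHull(img)
  m <- largest_component(EBImage::imageData(img) > 0)
  if (!any(m)) stop("no cell found: empty mask")
  cell_mask(m, calcium$pixel_size_um)
}
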