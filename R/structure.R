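#' Extract the t-tubule mask from the membrane channel
#'
#' Works directly in image space with no assumption on tubule orientation:
#' the temporal-mean membrane image is band-passed with a white top-hat
#' (disc structuring element about twice the tubule half-width), thresholded
#' by Otsu's rule computed over cell pixels only, and intersected with the
#' cell mask. The result is invariant to global intensity scaling of the
#' membrane channel.
#'
#' @param membrane A [timelapse_stack()] of the membrane-stain channel
#'   (already co-registered to the calcium grid).
#' @param cell A [cell_mask()].
#' @param config An [analysis_config()]; `tubule_filter_um` sets the top-hat
#'   scale.
#' @return A `tubule_mask` with `mask` and `coverage_fraction`
#'   (tubule pixels / cell pixels). An empty mask triggers a warning; the
#'   DNT stage then classifies the whole cell as detubulated.
#' @export
extract_tubule_mask <- function(membrane, cell, config = analysis_config()) {
  stopifnot(n_frames(membrane) >= 1, any(cell$mask))
  mean_img <- temporal_mean(membrane)
  rad <- max(1, round(um_to_px(config$tubule_filter_um, config)))
  hi <- max(mean_img)
  filt <- if (hi > 0) {
    EBImage::imageData(EBImage::whiteTopHat(mean_img / hi, disc_kernel(rad))) * hi
  } else {
    mean_img
  }
  vals <- filt[cell$mask]
  mask <- matrix(FALSE, nrow(mean_img), ncol(mean_img))
  if (max(vals) > min(vals)) {
    thr <- otsu_threshold(vals)
    mask <- filt > thr & cell$mask
  }
  if (!any(mask)) {
    warning("empty tubule mask: whole cell will be classified detubulated")
  }
  structure(list(mask = mask,
                 coverage_fraction = sum(mask) / cell$area_px),
            class = "tubule_mask")
}

#' @export
print.tubule_mask <- function(x, ...) {
  cat(sprintf("<tubule_mask> %d px, coverage %.1f%% of cell\n",
              sum(x$mask), 100 * x$coverage_fraction))
  invisible(x)
}

#' Measure the t-tubule period along a line profile
#'
#' Samples the image (or binary mask) along a line through a tubulated
#' region and returns the mean consecutive spacing between stripe centres.
#' Stripes are located as runs of the profile above its half-range level,
#' which handles both flat-topped binary masks and smooth intensity
#' profiles; each run centre is the stripe peak position.
#'
#' @param img Matrix: a temporal-mean membrane image or a tubule mask
#'   (logical matrices are accepted).
#' @param from,to Line endpoints `c(row, col)` in pixels; the line should
#'   cross at least three stripes.
#' @param pixel_size_um Pixel pitch.
#' @param min_run_px Runs narrower than this are ignored (suppresses
#'   single-sample noise crossings).
#' @return List with `period_um`, `period_px` and `n_peaks`.
#' @export
measure_tubule_period <- function(img, from, to, pixel_size_um = 6.5 / 44,
                                  min_run_px = 1) {
  if (is.logical(img)) img <- img * 1
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, ceiling(len) + 1L)
  rr <- seq(from[1], to[1], length.out = n)
  cc <- seq(from[2], to[2], length.out = n)
  prof <- bilinear_sample(img, rr, cc)
  step <- len / (n - 1)
  level <- (max(prof) + min(prof)) / 2
  above <- prof > level
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  wide <- (ends - starts + 1) * step >= min_run_px
  centers <- (starts[wide] + ends[wide]) / 2 * step
  if (length(centers) < 2) {
    stop("undefined period: fewer than 2 stripes along the profile")
  }
  period_px <- mean(diff(centers))
  list(period_um = period_px * pixel_size_um,
       period_px = period_px, n_peaks = length(centers))
}

#' Rasterize manually outlined nuclei
#'
#' Fills each polygon (vertices in pixel coordinates, `x` = column,
#' `y` = row, centres at integers) and clips to the cell mask. Polygons that
#' fall entirely outside the cell are dropped with a warning. Some cells
#' have no identifiable nucleus in the imaged plane: an empty outline list
#' is valid and yields `n_nuclei = 0`.
#'
#' @param outlines List of polygons (`list(x =, y =)`), e.g. from
#'   [read_nuclei_polygons()].
#' @param cell A [cell_mask()].
#' @return A `nucleus_mask` with `mask` and `n_nuclei` (connected-component
#'   count after clipping).
#' @export
rasterize_nuclei <- function(outlines, cell) {
  m <- matrix(FALSE, nrow(cell$mask), ncol(cell$mask))
  for (p in outlines) {
    rr <- max(1L, floor(min(p$y))):min(nrow(m), ceiling(max(p$y)))
    cc <- max(1L, floor(min(p$x))):min(ncol(m), ceiling(max(p$x)))
    if (!length(rr) || !length(cc)) next
    grid_r <- rep(rr, times = length(cc))
    grid_c <- rep(cc, each = length(rr))
    inside <- pracma::inpolygon(grid_c, grid_r, p$x, p$y, boundary = TRUE)
    filled <- matrix(FALSE, nrow(m), ncol(m))
    filled[cbind(grid_r[inside], grid_c[inside])] <- TRUE
    if (!any(filled & cell$mask)) {
      warning("nucleus outline entirely outside the cell mask; dropped")
      next
    }
    m <- m | (filled & cell$mask)
  }
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  structure(list(mask = m, n_nuclei = max(EBImage::imageData(lab))),
            class = "nucleus_mask")
}

#' Distance-to-nearest-tubule (DNT) map
#'
#' Exact Euclidean distance transform of the binary tubule mask: each cell
#' pixel gets the distance (in pixels) to the closest tubule pixel. The map
#' partitions the cell into epitubular (DNT = 0), paratubular
#' (0 < DNT <= `dnt_paratubular_max_px`) and detubulated
#' (DNT > `dnt_paratubular_max_px`) regions. With an empty tubule mask all
#' distances are `Inf` and the whole cell is detubulated.
#'
#' @param tubules A `tubule_mask` (or plain logical matrix). Tubule pixels
#'   outside the cell are excluded before the transform.
#' @param cell A [cell_mask()].
#' @param config An [analysis_config()]; supplies the paratubular bound,
#'   stored in pixels with the um equivalent derived from the pixel size.
#' @return A `dnt_map` with `dnt_px` (matrix, `NA` outside the cell),
#'   `category` (character matrix) and `paratubular_max_px`.
#' @export
compute_dnt_map <- function(tubules, cell, config = analysis_config()) {
  tub <- if (inherits(tubules, "tubule_mask")) tubules$mask else tubules
  stopifnot(any(cell$mask))
  tub <- tub & cell$mask
  if (any(tub)) {
    d <- EBImage::imageData(
      EBImage::distmap(EBImage::Image((!tub) * 1), metric = "euclidean"))
  } else {
    d <- matrix(Inf, nrow(cell$mask), ncol(cell$mask))
  }
  cat_map <- matrix(NA_character_, nrow(d), ncol(d))
  cat_map[cell$mask] <- dnt_category(d[cell$mask], config$dnt_paratubular_max_px)
  d[!cell$mask] <- NA_real_
  structure(list(dnt_px = d, category = cat_map,
                 paratubular_max_px = config$dnt_paratubular_max_px,
                 paratubular_max_um = px_to_um(config$dnt_paratubular_max_px,
                                               config)),
            class = "dnt_map")
}

#' Classify DNT values into spatial categories
#'
#' @param dnt_px Numeric DNT values in pixels.
#' @param max_px Paratubular upper bound in pixels.
#' @return Character vector: `"epitubular"`, `"paratubular"` or
#'   `"detubulated"`.
#' @export
dnt_category <- function(dnt_px, max_px = 5) {
  ifelse(dnt_px == 0, "epitubular",
         ifelse(dnt_px <= max_px, "paratubular", "detubulated"))
}

#' Mean DNT over the cell
#'
#' The expected distance from a randomly chosen cell pixel to the nearest
#' tubule — the reference against which the spark centre-of-mass DNT is
#' compared.
#'
#' @param dnt A `dnt_map`.
#' @param cell A [cell_mask()].
#' @return Mean DNT in pixels (`Inf` for a fully detubulated cell).
#' @export
mean_random_dnt <- function(dnt, cell) {
  mean(dnt$dnt_px[cell$mask])
}
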