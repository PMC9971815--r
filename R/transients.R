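#' Locate paced calcium transients and crop analysis windows
#'
#' Works on the paced part of the recording: the data are smoothed with a
#' 5 x 5 px spatial median filter and a 3-frame moving average, the
#' cell-average trace is peak-searched with a minimum separation of
#' `min_peak_separation_fraction` of one pacing period, and
#' `n_transients` consecutive transients are selected. Each is cropped to a
#' `crop_frames` window centred on its peak and paired with the pacing
#' rising edge immediately preceding the peak, which serves as the stimulus
#' reference time. Per window the function also computes the per-pixel
#' baseline map (mean of `baseline_window_frames` frames up until the edge),
#' the peak map (mean of `peak_window_frames` frames from the cell-average
#' peak) and the resulting peak dF/F0 map.
#'
#' @param calcium Background-subtracted calcium [timelapse_stack()].
#' @param pacing A [pacing_trace()] with detected edges; an unpaced
#'   recording is an error.
#' @param cell A [cell_mask()].
#' @param config An [analysis_config()].
#' @param start_periods How many pacing periods into the paced sequence the
#'   analysis segment starts (2 in the acquisition protocol; 0 when the
#'   stack already is the analysis segment).
#' @return List of `transient_window` objects.
#' @export
locate_transients <- function(calcium, pacing, cell,
                              config = analysis_config(),
                              start_periods = 2) {
  if (is.null(pacing) || length(pacing$edge_times_ms) == 0) {
    stop("unpaced recording: transient analysis requires pacing edges")
  }
  dt_ms <- 1000 / calcium$frame_rate_hz
  period_ms <- if (!is.na(pacing$period_ms)) pacing$period_ms else
    1000 / config$pacing_hz
  nt <- n_frames(calcium)
  n_win <- round(config$transient_window_s * 1000 / dt_ms)
  s0 <- floor(start_periods * period_ms / dt_ms) + 1L
  s1 <- min(nt, s0 + n_win - 1L)
  if (s1 - s0 + 1L < 3 * period_ms / dt_ms) {
    stop("paced segment too short: need at least ~4 pacing periods")
  }
  sub <- calcium$intensities[, , s0:s1, drop = FALSE]
  sub <- smooth_transient_stack(sub)
  d <- dim(sub)
  npx <- d[1] * d[2]
  flat <- matrix(sub, npx, d[3])
  trace <- colMeans(flat[which(cell$mask), , drop = FALSE])
  min_sep <- floor(config$min_peak_separation_fraction * period_ms / dt_ms)
  pk <- pracma::findpeaks(trace, minpeakdistance = min_sep,
                          minpeakheight = min(trace) + 0.5 * diff(range(trace)))
  if (is.null(pk) || nrow(pk) < config$n_transients) {
    stop(sprintf("found %d transient peaks; need %d",
                 if (is.null(pk)) 0L else nrow(pk), config$n_transients))
  }
  peaks <- sort(pk[, 2])
  half <- (config$crop_frames - 1L) %/% 2L
  # global frame -> acquisition time of frame start, in ms
  frame_time <- function(local) (calcium$origin_frame_index + s0 - 1L +
                                   local - 2L) * dt_ms
  windows <- list()
  i <- 1L
  while (i <= length(peaks) && length(windows) < config$n_transients) {
    p <- peaks[i]
    i <- i + 1L
    w0 <- p - half; w1 <- p + half
    if (w0 < 1L || w1 > d[3]) next
    p_time <- frame_time(p)
    edges <- pacing$edge_times_ms
    prev <- edges[edges <= p_time]
    if (!length(prev)) {
      warning("transient peak without a preceding pacing edge; dropped")
      windows <- list()  # consecutive run broken
      next
    }
    edge_ms <- max(prev)
    edge_local <- floor(edge_ms / dt_ms) + 1L -
      (calcium$origin_frame_index + s0 - 2L)
    if (edge_local - config$baseline_window_frames < w0) {
      warning("baseline window extends before the crop window; transient dropped")
      windows <- list()
      next
    }
    base_fr <- (edge_local - config$baseline_window_frames):(edge_local - 1L)
    peak_fr <- p:min(d[3], p + config$peak_window_frames - 1L)
    baseline_map <- matrix(rowMeans(flat[, base_fr, drop = FALSE]), d[1], d[2])
    peak_map <- matrix(rowMeans(flat[, peak_fr, drop = FALSE]), d[1], d[2])
    dff_peak <- matrix(NA_real_, d[1], d[2])
    ok <- cell$mask & baseline_map > 0
    dff_peak[ok] <- (peak_map[ok] - baseline_map[ok]) / baseline_map[ok]
    windows[[length(windows) + 1L]] <- structure(list(
      data = sub[, , w0:w1, drop = FALSE],
      frame_offset = w0 - 1L,          # window frame k = segment frame k + offset
      edge_time_ms = edge_ms,
      edge_frame = edge_local - w0 + 1L,
      peak_frame = p - w0 + 1L,
      time_ms = frame_time(w0:w1),
      baseline_map = baseline_map, peak_map = peak_map,
      dff_peak_map = dff_peak,
      frame_rate_hz = calcium$frame_rate_hz), class = "transient_window")
  }
  if (length(windows) < config$n_transients) {
    stop(sprintf("only %d usable transient windows; need %d",
                 length(windows), config$n_transients))
  }
  windows
}

#' @export
print.transient_window <- function(x, ...) {
  cat(sprintf("<transient_window> %d frames, edge at %.1f ms, peak frame %d\n",
              dim(x$data)[3], x$edge_time_ms, x$peak_frame))
  invisible(x)
}

#' Per-pixel transient time-to-half-maximum
#'
#' For each cell pixel the half-maximum level is
#' `F50 = (baseline + peak) / 2`. The first upward crossing of F50 on the
#' rising limb (between the stimulus edge and the cell-average peak frame)
#' is located and refined by linear interpolation between the last frame
#' below and the first frame at or above F50. T50 is the crossing time minus
#' the stimulus edge time, in ms. Pixels with `peak <= baseline`, no
#' crossing, or a level already above F50 at the stimulus are undefined
#' (`NA`).
#'
#' @param window A `transient_window` from [locate_transients()].
#' @param cell A [cell_mask()].
#' @return Matrix of T50 values in ms (`NA` where undefined).
#' @export
compute_t50_map <- function(window, cell) {
  d <- dim(window$data)
  npx <- d[1] * d[2]
  flat <- matrix(window$data, npx, d[3])
  f50 <- (window$baseline_map + window$peak_map) / 2
  search <- window$edge_frame:window$peak_frame
  seg <- flat[, search, drop = FALSE]
  above <- seg >= as.vector(f50)
  first <- max.col(above, ties.method = "first")
  valid <- as.vector(cell$mask) &
    as.vector(window$peak_map > window$baseline_map) &
    above[cbind(seq_len(npx), first)] &   # a crossing exists
    first > 1L                            # not already above at the stimulus
  k <- search[first]                      # frame of first value >= F50
  prev_v <- flat[cbind(seq_len(npx), pmax(k - 1L, 1L))]
  cross_v <- flat[cbind(seq_len(npx), k)]
  frac <- (as.vector(f50) - prev_v) / (cross_v - prev_v)
  t_prev <- window$time_ms[pmax(k - 1L, 1L)]
  dt_ms <- 1000 / window$frame_rate_hz
  t50 <- t_prev + frac * dt_ms - window$edge_time_ms
  t50[!valid] <- NA_real_
  matrix(t50, d[1], d[2])
}

#' Aggregate per-transient T50 maps
#'
#' Pixel-wise mean and standard deviation across transients, defined where
#' every per-transient map is defined.
#'
#' @param maps List of at least two T50 matrices from [compute_t50_map()].
#' @return A `t50_map` with `per_transient`, `mean`, `sd` and `valid`.
#' @export
aggregate_t50_maps <- function(maps) {
  stopifnot(length(maps) >= 2)
  stack <- simplify2array(maps)
  valid <- apply(!is.na(stack), c(1, 2), all)
  mean_map <- apply(stack, c(1, 2), mean)
  sd_map <- apply(stack, c(1, 2), stats::sd)
  mean_map[!valid] <- NA_real_
  sd_map[!valid] <- NA_real_
  structure(list(per_transient = maps, mean = mean_map, sd = sd_map,
                 valid = valid), class = "t50_map")
}

#' @export
print.t50_map <- function(x, ...) {
  cat(sprintf("<t50_map> %d transients, %d valid px, median %.2f ms\n",
              length(x$per_transient), sum(x$valid),
              stats::median(x$mean[x$valid])))
  invisible(x)
}

#' Regional T50 summary and dyssynchrony index
#'
#' Assuming approximate alignment of the cell with the horizontal axis, the
#' cell length is taken from the first and last columns with a defined T50;
#' the central ROI spans the middle half of that length and the two outer
#' ROIs (grouped) the end quarters. Nuclear pixels are excluded from the
#' central/outer/exonuclear medians. The dyssynchrony index is the IQR of
#' T50 over all defined cell pixels.
#'
#' @param t50 A `t50_map` (its `mean` layer is summarized) or a single T50
#'   matrix.
#' @param cell A [cell_mask()].
#' @param nuclei Optional `nucleus_mask`; without one (or with
#'   `n_nuclei = 0`) the nuclear fields are `NA` (missing, not 0).
#' @return A `regional_t50_summary` list: medians (ms) for cell, nucleus,
#'   exonuclear, central and outer regions; `delta_nucleus_ms`
#'   (nucleus - exonuclear); `delta_central_outer_ms` (central - outer);
#'   `dyssynchrony_iqr_ms`; pixel counts per region.
#' @export
summarize_regions <- function(t50, cell, nuclei = NULL) {
  m <- if (inherits(t50, "t50_map")) t50$mean else t50
  def <- !is.na(m) & cell$mask
  if (!any(def)) stop("T50 map undefined on every cell pixel")
  cols <- which(colSums(def) > 0)
  c0 <- min(cols); c1 <- max(cols)
  len <- c1 - c0 + 1L
  q <- len / 4
  central_cols <- seq_len(ncol(m)) >= c0 + q & seq_len(ncol(m)) < c1 + 1 - q
  central <- def & matrix(central_cols, nrow(m), ncol(m), byrow = TRUE)
  outer <- def & !central
  nuc <- if (!is.null(nuclei) && nuclei$n_nuclei > 0) nuclei$mask else
    matrix(FALSE, nrow(m), ncol(m))
  med <- function(sel) if (any(sel)) stats::median(m[sel]) else NA_real_
  median_nucleus <- if (any(nuc & def)) med(nuc & def) else NA_real_
  median_exonuclear <- med(def & !nuc)
  median_central <- med(central & !nuc)
  median_outer <- med(outer & !nuc)
  vals <- m[def]
  structure(list(
    median_cell_ms = stats::median(vals),
    median_nucleus_ms = median_nucleus,
    median_exonuclear_ms = median_exonuclear,
    median_central_ms = median_central,
    median_outer_ms = median_outer,
    delta_nucleus_ms = median_nucleus - median_exonuclear,
    delta_central_outer_ms = median_central - median_outer,
    dyssynchrony_iqr_ms = stats::IQR(vals),
    n_px = sum(def), n_px_nucleus = sum(nuc & def),
    n_px_central = sum(central & !nuc), n_px_outer = sum(outer & !nuc)),
    class = "regional_t50_summary")
}

#' @export
print.regional_t50_summary <- function(x, ...) {
  cat("<regional_t50_summary>\n")
  cat(sprintf("  cell median %.2f ms, IQR %.2f ms\n",
              x$median_cell_ms, x$dyssynchrony_iqr_ms))
  cat(sprintf("  nucleus - exonuclear: %.2f ms; central - outer: %.2f ms\n",
              x$delta_nucleus_ms, x$delta_central_outer_ms))
  invisible(x)
}

#' Linear fit of T50 against tubule distance
#'
#' Ordinary least squares of per-pixel T50 (ms) on DNT (px), separately for
#' the tubulated (DNT <= paratubular bound, i.e. epitubular + paratubular)
#' and detubulated (DNT > bound) pixel populations, with the 95% CI of the
#' slope from its standard error (t distribution).
#'
#' @param t50 A `t50_map` or T50 matrix.
#' @param dnt A `dnt_map`.
#' @param min_n Minimum pixels per class for a reported fit.
#' @return data.frame with one row per class: `slope_ms_per_px`,
#'   `intercept_ms`, `ci_lo`, `ci_hi`, `n_px`. Classes with too few pixels
#'   or degenerate DNT variance get `NA` estimates.
#' @export
fit_t50_vs_dnt <- function(t50, dnt, min_n = 3) {
  m <- if (inherits(t50, "t50_map")) t50$mean else t50
  classes <- list(
    tubulated = !is.na(dnt$dnt_px) & dnt$dnt_px <= dnt$paratubular_max_px,
    detubulated = !is.na(dnt$dnt_px) & dnt$dnt_px > dnt$paratubular_max_px)
  rows <- lapply(names(classes), function(k) {
    sel <- classes[[k]] & !is.na(m) & is.finite(dnt$dnt_px)
    x <- dnt$dnt_px[sel]; y <- m[sel]
    if (sum(sel) < min_n || stats::sd(x) == 0) {
      return(data.frame(class = k, slope_ms_per_px = NA_real_,
                        intercept_ms = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_px = sum(sel)))
    }
    fit <- stats::lm(y ~ x)
    ci <- stats::confint(fit, "x", level = 0.95)
    data.frame(class = k, slope_ms_per_px = unname(stats::coef(fit)["x"]),
               intercept_ms = unname(stats::coef(fit)[1]),
               ci_lo = ci[1], ci_hi = ci[2], n_px = sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("t50_dnt_fit", class(out))
  out
}
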