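#' Specify a synthetic phantom recording
#'
#' Defines a ground-truthed dual-channel phantom: an ellipsoidal
#' cardiomyocyte with a periodic transverse-tubule lattice (plus optional
#' longitudinal elements and detubulated patches), up to two nuclei, paced
#' global calcium transients with a spatially varying onset-delay field,
#' stochastic localized sparks with DNT-dependent rates, and camera noise.
#' The seed fully determines the output.
#'
#' The default field of view (256 x 128 px at the instrument pixel size,
#' i.e. 37.8 x 18.9 um) and cell size are reduced relative to a full-scale
#' acquisition so that a default phantom renders at desk scale; every length
#' scales consistently through `pixel_size_um`.
#'
#' @param fov_px Frame size `c(rows, cols)`.
#' @param length_um,width_um Cell major/minor diameters.
#' @param orientation_deg Cell long-axis angle to the horizontal.
#' @param pixel_size_um,frame_rate_hz Acquisition geometry and rate.
#' @param tubule_period_um Transverse-tubule spacing (1.8-2 um in adult
#'   ventricular myocytes); rasterized to the nearest whole pixel.
#' @param tubule_width_um Width of the rendered tubule stripes. This is the
#'   width of the stained/masked tubule image (diffraction-broadened), not
#'   the ~250 nm anatomical tubule: 0.7 um stripes at a 2 um period give the
#'   ~35% masked-tubule coverage and ~1.5 px mean random DNT seen in real
#'   recordings.
#' @param longitudinal_fraction Rough fraction of tubule elements running
#'   along the cell axis.
#' @param detub_patches,detub_radius_um Number and radius of detubulated
#'   patches punched out of the lattice.
#' @param n_nuclei 0-2 nuclei (tubule-free, ellipses along the axis).
#' @param nucleus_axes_um Nucleus major/minor diameters.
#' @param f0_dn Baseline calcium-channel intensity inside the cell (digital
#'   numbers); `f0_edge_falloff` dims it towards the cell border.
#' @param f0_edge_falloff Relative baseline dimming at the cell border.
#' @param background_dn Extracellular/camera background level.
#' @param noise_sd_dn Gaussian read-noise SD; `poisson_noise` adds shot
#'   noise.
#' @param poisson_noise Add Poisson shot noise on top of the read noise.
#' @param transient_shape `"expprod"` — the product form
#'   `A (1 - exp(-t/tau_rise)) exp(-t/tau_decay)` — or `"ramp"` (linear rise
#'   over `ramp_rise_ms`, then exponential decay), which has an exactly
#'   known half-rise time.
#' @param amplitude_dff Transient peak dF/F0.
#' @param tau_rise_ms,tau_decay_ms,ramp_rise_ms Kinetic constants.
#' @param base_delay_ms Uniform latency from the stimulus edge to the onset
#'   of the local rise.
#' @param nuclear_extra_delay_ms Additional onset delay on nuclear pixels.
#' @param end_offset_ms Onset-delay offset of the outer quarters of the cell
#'   relative to the central half (negative = ends rise earlier).
#' @param dnt_delay_ms_per_px Optional DNT-proportional delay;
#'   `dnt_delay_detubulated_only` restricts it to detubulated pixels.
#' @param dnt_delay_detubulated_only See above.
#' @param spark_rate_per_100um2_s Named spark rates (events per 100 um^2 per
#'   second) for the epitubular/paratubular/detubulated categories. The
#'   defaults reproduce the spontaneous rates seen in healthy rat
#'   ventricular myocytes (~100 sparks per 12.7 s in a ~2500 um^2 cell,
#'   concentrated on the tubules, with the paratubular rate ~60% lower than
#'   the epitubular one).
#' @param spark_amplitude_mean,spark_amplitude_sd Spark dF/F0 amplitude
#'   distribution (truncated normal).
#' @param spark_fwhm_um_mean,spark_fwhm_um_sd Spatial FWHM distribution.
#' @param spark_fdhm_ms_mean,spark_fdhm_ms_sd Duration (FDHM) distribution.
#' @param spark_placement `"poisson"` — events drawn independently, as the
#'   spontaneous release process — or `"spaced"`, which greedily thins
#'   spatio-temporally overlapping draws so every rendered event is
#'   isolated (the regime for benchmarking detector recall/precision
#'   against per-event ground truth; overlapping events have no uniquely
#'   attributable truth).
#' @param pacing_hz,pacing_pulse_ms,first_edge_ms Stimulation train; edges
#'   run through the paced segment only.
#' @param paced_s,gap_s,unpaced_s Durations of the paced segment, a
#'   stimulation-free settling gap, and the unpaced segment used for spark
#'   analysis.
#' @param channel_scale_ratio Relative magnification applied when rendering
#'   the membrane channel (1 = channels share the grid).
#' @param channel_shift_px Integer misalignment `c(rows, cols)` applied to
#'   the membrane channel.
#' @param seed Integer seed; determines masks, spark draws and noise.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(fov_px = c(128L, 256L),
                         length_um = 34, width_um = 14,
                         orientation_deg = 0,
                         pixel_size_um = 6.5 / 44, frame_rate_hz = 395,
                         tubule_period_um = 2.0, tubule_width_um = 0.7,
                         longitudinal_fraction = 0.08,
                         detub_patches = 2L, detub_radius_um = 2.5,
                         n_nuclei = 1L, nucleus_axes_um = c(7, 3),
                         f0_dn = 100, f0_edge_falloff = 0.15,
                         background_dn = 10,
                         noise_sd_dn = 20, poisson_noise = FALSE,
                         transient_shape = c("expprod", "ramp"),
                         amplitude_dff = 1.5,
                         tau_rise_ms = 10, tau_decay_ms = 500,
                         ramp_rise_ms = 25,
                         base_delay_ms = 20,
                         nuclear_extra_delay_ms = 3.5,
                         end_offset_ms = -2,
                         dnt_delay_ms_per_px = 0,
                         dnt_delay_detubulated_only = TRUE,
                         spark_rate_per_100um2_s = c(epitubular = 0.5,
                                                     paratubular = 0.2,
                                                     detubulated = 0.08),
                         spark_amplitude_mean = 0.6, spark_amplitude_sd = 0.15,
                         spark_fwhm_um_mean = 2.0, spark_fwhm_um_sd = 0.3,
                         spark_fdhm_ms_mean = 28, spark_fdhm_ms_sd = 6,
                         spark_placement = c("poisson", "spaced"),
                         pacing_hz = 0.5, pacing_pulse_ms = 2,
                         first_edge_ms = 700,
                         paced_s = 0, gap_s = 0, unpaced_s = 5.06,
                         channel_scale_ratio = 1,
                         channel_shift_px = c(0L, 0L),
                         seed = 1L) {
  spec <- as.list(environment())
  spec$transient_shape <- match.arg(transient_shape)
  spec$spark_placement <- match.arg(spark_placement)
  stopifnot(all(fov_px >= 16), length_um > 0, width_um > 0,
            tubule_period_um > 0, tubule_width_um > 0,
            n_nuclei %in% 0:2, f0_dn > 0, noise_sd_dn >= 0,
            all(spark_rate_per_100um2_s >= 0), paced_s >= 0, gap_s >= 0,
            unpaced_s >= 0, paced_s + unpaced_s > 0)
  if (length_um / pixel_size_um > fov_px[2] - 4 ||
      width_um / pixel_size_um > fov_px[1] - 4) {
    stop("cell larger than the field of view")
  }
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px, cell %g x %g um, seed %d\n",
              x$fov_px[1], x$fov_px[2], x$length_um, x$width_um, x$seed))
  invisible(x)
}

#' Analysis configuration matched to a phantom
#'
#' @param spec A [phantom_spec()].
#' @param block_len_frames,n_blocks Spark block structure (desk-scale
#'   defaults: the unpaced segment tiled into 500-frame blocks).
#' @param ... Further overrides passed to [analysis_config()].
#' @return An [analysis_config()].
#' @export
phantom_config <- function(spec, block_len_frames = 500,
                           n_blocks = NULL, ...) {
  n_unpaced <- round(spec$unpaced_s * spec$frame_rate_hz)
  if (is.null(n_blocks)) n_blocks <- max(1L, n_unpaced %/% block_len_frames)
  analysis_config(frame_rate_hz = spec$frame_rate_hz,
                  pixel_size_um = spec$pixel_size_um,
                  camera_pixel_um = NULL, magnification = NULL,
                  pacing_hz = spec$pacing_hz,
                  pacing_pulse_ms = spec$pacing_pulse_ms,
                  block_len_frames = block_len_frames, n_blocks = n_blocks,
                  channel_scale_ratio = spec$channel_scale_ratio, ...)
}

# Rotated cell-axis coordinates (u along the long axis, v across), in px,
# relative to the frame centre.
.axis_coords <- function(spec) {
  nr <- spec$fov_px[1]; nc <- spec$fov_px[2]
  th <- spec$orientation_deg * pi / 180
  r <- matrix(seq_len(nr) - (nr + 1) / 2, nr, nc)
  c <- matrix(rep(seq_len(nc) - (nc + 1) / 2, each = nr), nr, nc)
  list(u = c * cos(th) + r * sin(th), v = -c * sin(th) + r * cos(th))
}

#' Generate the ground truth of a phantom
#'
#' Rasterizes the cell, tubule and nucleus masks, derives the true DNT map
#' (through the same oracle-verified distance transform the pipeline uses),
#' builds the per-pixel transient onset-delay field and its analytic
#' half-rise (T50) truth, and draws the spark table from the configured
#' DNT-category rates. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth` with masks, `dnt`, `delay_ms`, `t50_ms`
#'   (stimulus-referenced truth field), `f0_map` and `sparks` (truth table).
#' @export
generate_phantom <- function(spec) {
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  ax <- .axis_coords(spec)
  a <- spec$length_um / 2 / px
  b <- spec$width_um / 2 / px
  rho2 <- (ax$u / a)^2 + (ax$v / b)^2
  cell <- rho2 <= 1
  cfg <- phantom_config(spec)

  # transverse stripes at a whole-pixel period
  period_px <- max(2L, round(spec$tubule_period_um / px))
  width_px <- max(1L, round(spec$tubule_width_um / px))
  phase <- (round(ax$u) %% period_px)
  tub <- cell & phase < width_px
  # longitudinal elements: short axis-parallel bars bridging stripes
  n_long <- round(spec$longitudinal_fraction * spec$length_um /
                    spec$tubule_period_um)
  if (n_long > 0) {
    for (i in seq_len(n_long)) {
      u0 <- stats::runif(1, -0.8 * a, 0.8 * a)
      v0 <- stats::runif(1, -0.8 * b, 0.8 * b)
      bar <- cell & abs(ax$v - v0) < width_px &
        ax$u >= u0 & ax$u <= u0 + 2 * period_px
      tub <- tub | bar
    }
  }
  # detubulated patches
  if (spec$detub_patches > 0) {
    rad <- spec$detub_radius_um / px
    for (i in seq_len(spec$detub_patches)) {
      u0 <- stats::runif(1, -0.7 * a, 0.7 * a)
      v0 <- stats::runif(1, -0.6 * b, 0.6 * b)
      tub <- tub & !(((ax$u - u0)^2 + (ax$v - v0)^2) <= rad^2)
    }
  }
  # nuclei: tubule-free ellipses along the axis
  nuc <- matrix(FALSE, spec$fov_px[1], spec$fov_px[2])
  if (spec$n_nuclei > 0) {
    an <- spec$nucleus_axes_um[1] / 2 / px
    bn <- spec$nucleus_axes_um[2] / 2 / px
    centers <- if (spec$n_nuclei == 1) 0 else c(-a / 3, a / 3)
    for (u0 in centers) {
      nuc <- nuc | (((ax$u - u0) / an)^2 + (ax$v / bn)^2 <= 1)
    }
    nuc <- nuc & cell
    tub <- tub & !nuc
  }
  cellm <- cell_mask(cell, px)
  dnt <- compute_dnt_map(tub, cellm, cfg)

  # onset-delay field (quantized to 0.05 ms for exact-truth bookkeeping)
  delay <- matrix(NA_real_, spec$fov_px[1], spec$fov_px[2])
  delay[cell] <- spec$base_delay_ms
  u_cell <- ax$u[cell]
  outer_q <- abs(ax$u) > a / 2   # beyond half the semi-length = end quarters
  delay[cell & outer_q] <- delay[cell & outer_q] + spec$end_offset_ms
  delay[nuc] <- delay[nuc] + spec$nuclear_extra_delay_ms
  if (spec$dnt_delay_ms_per_px != 0) {
    sel <- if (spec$dnt_delay_detubulated_only) {
      cell & dnt$category == "detubulated"
    } else cell
    sel <- sel & is.finite(dnt$dnt_px)
    delay[sel] <- delay[sel] + spec$dnt_delay_ms_per_px * dnt$dnt_px[sel]
  }
  delay <- round(delay / 0.05) * 0.05
  half_rise <- analytic_t50_oracle(spec)
  t50 <- delay + half_rise

  # baseline map with edge falloff
  f0 <- matrix(0, spec$fov_px[1], spec$fov_px[2])
  f0[cell] <- spec$f0_dn * (1 - spec$f0_edge_falloff * rho2[cell])

  truth <- structure(list(
    spec = spec, config = cfg, cell = cellm,
    tubules = structure(list(mask = tub,
                             coverage_fraction = sum(tub) / sum(cell)),
                        class = "tubule_mask"),
    nuclei = structure(list(mask = nuc,
                            n_nuclei = if (any(nuc)) spec$n_nuclei else 0L),
                       class = "nucleus_mask"),
    dnt = dnt, delay_ms = delay, half_rise_ms = half_rise, t50_ms = t50,
    f0_map = f0, sparks = NULL), class = "phantom_truth")
  truth$sparks <- .draw_spark_truth(truth)
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> cell %d px, tubule coverage %.0f%%, %d sparks\n",
              x$cell$area_px, 100 * x$tubules$coverage_fraction,
              nrow(x$sparks)))
  invisible(x)
}

# Poisson spark draws per DNT category, uniform placement within category.
.draw_spark_truth <- function(truth) {
  spec <- truth$spec
  px <- spec$pixel_size_um
  n_unpaced <- round(spec$unpaced_s * spec$frame_rate_hz)
  dt_ms <- 1000 / spec$frame_rate_hz
  rows <- list()
  for (cat in names(spec$spark_rate_per_100um2_s)) {
    pix <- which(truth$dnt$category == cat & truth$cell$mask)
    if (!length(pix)) next
    area_um2 <- length(pix) * px^2
    lambda <- spec$spark_rate_per_100um2_s[[cat]] * area_um2 / 100 *
      spec$unpaced_s
    n <- stats::rpois(1, lambda)
    if (n == 0) next
    at <- sample(pix, n, replace = TRUE)
    ar <- arrayInd(at, dim(truth$cell$mask))
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat,
        com_row = ar[i, 1] + stats::runif(1, -0.5, 0.5),
        com_col = ar[i, 2] + stats::runif(1, -0.5, 0.5),
        onset_frame = sample.int(n_unpaced, 1),
        amplitude = max(0.2, stats::rnorm(1, spec$spark_amplitude_mean,
                                          spec$spark_amplitude_sd)),
        fwhm_um = max(1.0, stats::rnorm(1, spec$spark_fwhm_um_mean,
                                        spec$spark_fwhm_um_sd)),
        fdhm_ms = max(10, stats::rnorm(1, spec$spark_fdhm_ms_mean,
                                       spec$spark_fdhm_ms_sd)))
    }
  }
  if (!length(rows)) {
    return(data.frame(category = character(0), com_row = numeric(0),
                      com_col = numeric(0), onset_frame = integer(0),
                      amplitude = numeric(0), fwhm_um = numeric(0),
                      fdhm_ms = numeric(0), peak_frame = integer(0),
                      truncated = logical(0), id = integer(0)))
  }
  df <- do.call(rbind, rows)
  if (spec$spark_placement == "spaced" && nrow(df) > 1) {
    ord <- order(df$onset_frame)
    df <- df[ord, ]
    keep <- rep(TRUE, nrow(df))
    for (i in 2:nrow(df)) {
      prev <- which(keep[seq_len(i - 1L)])
      if (!length(prev)) next
      d_px <- sqrt((df$com_row[prev] - df$com_row[i])^2 +
                     (df$com_col[prev] - df$com_col[i])^2)
      d_ms <- (df$onset_frame[i] - df$onset_frame[prev]) * dt_ms
      clash_px <- 1.2 * (df$fwhm_um[prev] + df$fwhm_um[i]) / px
      clash_ms <- 2 * (df$fdhm_ms[prev] + df$fdhm_ms[i])
      if (any(d_px < clash_px & d_ms < clash_ms)) keep[i] <- FALSE
    }
    df <- df[keep, , drop = FALSE]
  }
  df$id <- seq_len(nrow(df))
  # peak time of the spark time course and a truncation flag
  kin <- lapply(seq_len(nrow(df)), function(i) .spark_kinetics(df$fdhm_ms[i]))
  t_peak_ms <- vapply(kin, function(k) k$t_peak_ms, numeric(1))
  df$peak_frame <- df$onset_frame + round(t_peak_ms / dt_ms)
  span_frames <- ceiling((t_peak_ms + 3 * df$fdhm_ms) / dt_ms)
  df$truncated <- df$onset_frame <= 2 |
    (df$onset_frame + span_frames) > n_unpaced
  df[order(df$onset_frame), c("id", "category", "com_row", "com_col",
                              "onset_frame", "peak_frame", "amplitude",
                              "fwhm_um", "fdhm_ms", "truncated")]
}

# Spark time course: (1 - exp(-t/tau_r)) exp(-t/tau_d), normalized to peak 1,
# with tau_d solved so the full duration at half maximum equals fdhm_ms.
.spark_kinetics <- function(fdhm_ms, tau_rise_ms = fdhm_ms / 6) {
  shape <- function(t, td) (1 - exp(-t / tau_rise_ms)) * exp(-t / td)
  fdhm_of <- function(td) {
    tp <- tau_rise_ms * log(1 + td / tau_rise_ms)
    pk <- shape(tp, td)
    t1 <- stats::uniroot(function(t) shape(t, td) - pk / 2, c(0, tp),
                         tol = 1e-8)$root
    t2 <- stats::uniroot(function(t) shape(t, td) - pk / 2,
                         c(tp, tp + 60 * td), tol = 1e-8)$root
    t2 - t1
  }
  td <- stats::uniroot(function(td) fdhm_of(td) - fdhm_ms,
                       c(fdhm_ms / 10, fdhm_ms * 50), tol = 1e-6)$root
  t_peak <- tau_rise_ms * log(1 + td / tau_rise_ms)
  peak <- shape(t_peak, td)
  list(tau_rise_ms = tau_rise_ms, tau_decay_ms = td, t_peak_ms = t_peak,
       value = function(t) ifelse(t <= 0, 0, shape(t, td) / peak))
}

# Normalized transient time course (peak 1) as a function of ms since onset.
.transient_shape_fn <- function(spec) {
  if (spec$transient_shape == "ramp") {
    rise <- spec$ramp_rise_ms
    td <- spec$tau_decay_ms
    function(t) ifelse(t <= 0, 0,
                       ifelse(t <= rise, t / rise, exp(-(t - rise) / td)))
  } else {
    tr <- spec$tau_rise_ms; td <- spec$tau_decay_ms
    tp <- tr * log(1 + td / tr)
    pk <- (1 - exp(-tp / tr)) * exp(-tp / td)
    function(t) ifelse(t <= 0, 0, (1 - exp(-t / tr)) * exp(-t / td) / pk)
  }
}

#' Analytic half-rise time of the phantom transient
#'
#' Solves `F(t) = (F_peak + F0) / 2` on the rising limb of the phantom's
#' transient model, returning the time from stimulus to half-maximum for a
#' pixel with onset delay `delay_ms`. For the `"ramp"` shape this is exactly
#' `delay + ramp_rise / 2`; for the product form the crossing is found
#' numerically (bisection to 1e-6 ms). Pure function of the spec.
#'
#' @param spec A [phantom_spec()].
#' @param delay_ms Onset delay(s) of the pixel(s), ms after the stimulus
#'   edge.
#' @return Half-rise time(s) in ms after the stimulus edge.
#' @export
analytic_t50_oracle <- function(spec, delay_ms = 0) {
  if (spec$transient_shape == "ramp") {
    return(delay_ms + spec$ramp_rise_ms / 2)
  }
  tr <- spec$tau_rise_ms; td <- spec$tau_decay_ms
  if (tr <= 0 || td <= 0) stop("non-monotone rise parameters")
  tp <- tr * log(1 + td / tr)
  f <- function(t) (1 - exp(-t / tr)) * exp(-t / td)
  pk <- f(tp)
  root <- stats::uniroot(function(t) f(t) - pk / 2, c(0, tp),
                         tol = 1e-9)$root
  delay_ms + root
}

#' Render a phantom into a recording bundle
#'
#' Calcium channel: baseline map times
#' `1 + transient dF/F0 (per-pixel onset delay) + injected sparks`
#' (separable spatial Gaussian x the piecewise-exponential time course),
#' plus background and noise, rounded to integer digital numbers. Membrane
#' channel: the tubule/cell structure image (optionally rendered at a
#' relative channel magnification and misalignment), plus noise. The pacing
#' trace is a top-hat train over the paced segment, sampled at 1 kHz.
#'
#' @param truth A [generate_phantom()] result.
#' @param noise Set `FALSE` to render noiselessly regardless of the spec.
#' @param channels `"both"` renders the full membrane channel with noise;
#'   `"calcium"` renders the membrane as the noise-free structure image only
#'   (one allocation), for workflows that never touch it.
#' @return A [recording_bundle()]; the frame layout (paced/gap/unpaced
#'   frame counts) is attached as attribute `"layout"`.
#' @export
render_recording <- function(truth, noise = TRUE,
                             channels = c("both", "calcium")) {
  channels <- match.arg(channels)
  spec <- truth$spec
  set.seed(spec$seed + 1000003L)
  nr <- spec$fov_px[1]; nc <- spec$fov_px[2]
  npx <- nr * nc
  fr <- spec$frame_rate_hz
  dt_ms <- 1000 / fr
  n_paced <- round(spec$paced_s * fr)
  n_gap <- round(spec$gap_s * fr)
  n_unpaced <- round(spec$unpaced_s * fr)
  nt <- n_paced + n_gap + n_unpaced
  t_ms <- (seq_len(nt) - 1) * dt_ms

  base <- spec$background_dn + as.vector(truth$f0_map)
  cal <- matrix(base, npx, nt)

  # paced transients: evaluate per unique onset delay
  edges <- numeric(0)
  if (n_paced > 0) {
    period_ms <- 1000 / spec$pacing_hz
    edges <- seq(spec$first_edge_ms, n_paced * dt_ms - 1, by = period_ms)
    shape <- .transient_shape_fn(spec)
    cellv <- which(truth$cell$mask)
    delays <- truth$delay_ms[cellv]
    f0v <- truth$f0_map[cellv]
    for (d in unique(delays)) {
      resp <- rep(0, nt)
      for (e in edges) resp <- resp + shape(t_ms - e - d)
      sel <- cellv[delays == d]
      cal[sel, ] <- cal[sel, ] + spec$amplitude_dff * f0v[delays == d] %o% resp
    }
  }

  # sparks in the unpaced segment
  if (nrow(truth$sparks) > 0) {
    px <- spec$pixel_size_um
    for (i in seq_len(nrow(truth$sparks))) {
      s <- truth$sparks[i, ]
      kin <- .spark_kinetics(s$fdhm_ms)
      span <- ceiling((kin$t_peak_ms + 6 * s$fdhm_ms) / dt_ms)
      fr0 <- n_paced + n_gap + s$onset_frame
      frames <- fr0:min(nt, fr0 + span)
      tloc <- (frames - fr0) * dt_ms
      sigma_px <- s$fwhm_um / 2.3548 / px
      half_w <- ceiling(3 * sigma_px)
      rr <- max(1, round(s$com_row) - half_w):min(nr, round(s$com_row) + half_w)
      cc <- max(1, round(s$com_col) - half_w):min(nc, round(s$com_col) + half_w)
      gr <- exp(-((rr - s$com_row)^2) / (2 * sigma_px^2))
      gc <- exp(-((cc - s$com_col)^2) / (2 * sigma_px^2))
      spatial <- as.vector(gr %o% gc) * s$amplitude
      pix <- as.vector(outer(rr, (cc - 1) * nr, "+"))
      f0pix <- as.vector(truth$f0_map)[pix]
      cal[pix, frames] <- cal[pix, frames] +
        (spatial * f0pix) %o% kin$value(tloc)
    }
  }

  if (noise && spec$noise_sd_dn > 0) {
    cal <- cal + stats::rnorm(length(cal), 0, spec$noise_sd_dn)
  }
  if (noise && spec$poisson_noise) {
    cal <- matrix(stats::rpois(length(cal), pmax(cal, 0)), npx, nt)
  }
  cal <- round(pmax(cal, 0))

  # membrane channel: static structure + noise
  struct <- spec$background_dn + 30 * truth$cell$mask + 90 * truth$tubules$mask
  struct[truth$nuclei$mask] <- spec$background_dn + 12
  if (spec$channel_scale_ratio != 1) {
    struct <- rescale_about_center(struct, 1 / spec$channel_scale_ratio)
  }
  if (any(spec$channel_shift_px != 0)) {
    struct <- shift_matrix(struct, spec$channel_shift_px,
                           fill = spec$background_dn)
  }
  if (channels == "both") {
    mem <- matrix(as.vector(struct), npx, nt)
    if (noise && spec$noise_sd_dn > 0) {
      mem <- mem + stats::rnorm(length(mem), 0, spec$noise_sd_dn)
    }
    mem <- round(pmax(mem, 0))
  } else {
    mem <- array(round(pmax(struct, 0)), c(nr, nc, nt))
  }

  # pacing trace at 1 kHz
  total_ms <- nt * dt_ms
  samp_t <- seq(0, total_ms, by = 1)
  level <- rep(0L, length(samp_t))
  for (e in edges) {
    level[samp_t >= e & samp_t < e + spec$pacing_pulse_ms] <- 1L
  }
  pac <- pacing_trace(samp_t, level)

  bundle <- recording_bundle(
    timelapse_stack(array(cal, c(nr, nc, nt)), "calcium", fr,
                    spec$pixel_size_um),
    timelapse_stack(array(mem, c(nr, nc, nt)), "membrane", fr,
                    spec$pixel_size_um),
    pacing = if (length(edges)) pac else NULL,
    metadata = list(phantom_seed = spec$seed))
  attr(bundle, "layout") <- c(paced = n_paced, gap = n_gap,
                              unpaced = n_unpaced)
  bundle
}

#' Write a rendered phantom to disk
#'
#' Emits the two channels as 16-bit multi-frame TIFFs, the pacing trace as
#' CSV, the truth tables as CSVs and the spec as YAML for provenance.
#'
#' @param truth A [generate_phantom()] result.
#' @param bundle The matching [render_recording()] output.
#' @param out_dir Output directory.
#' @return Files written, invisibly.
#' @export
write_phantom <- function(truth, bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(
    calcium = file.path(out_dir, "calcium.tif"),
    membrane = file.path(out_dir, "membrane.tif"),
    pacing = file.path(out_dir, "pacing.csv"),
    sparks = file.path(out_dir, "truth_sparks.csv"),
    t50 = file.path(out_dir, "truth_t50_ms.csv"),
    spec = file.path(out_dir, "phantom_spec.yaml"))
  write_tiff_stack(bundle$calcium, files["calcium"])
  write_tiff_stack(bundle$membrane, files["membrane"])
  pac <- if (!is.null(bundle$pacing)) bundle$pacing else
    pacing_trace(c(0, 1), c(0, 0))
  utils::write.csv(data.frame(time_ms = pac$time_ms, level = pac$level),
                   files["pacing"], row.names = FALSE)
  utils::write.csv(truth$sparks, files["sparks"], row.names = FALSE)
  utils::write.csv(truth$t50_ms, files["t50"], row.names = FALSE)
  sp <- truth$spec
  sp <- sp[!vapply(sp, is.function, TRUE)]
  class(sp) <- NULL
  yaml::write_yaml(sp, files["spec"])
  invisible(files)
}
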