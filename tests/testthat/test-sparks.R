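# A hand-built detection segment: 24 x 24 px, one 200-frame block, uniform
# baseline. Useful for exercising prepare/characterize against direct
# arithmetic.
make_flat_stack <- function(value = 100, d = c(24L, 24L, 200L)) {
  timelapse_stack(array(value, d), frame_rate_hz = 395,
                  pixel_size_um = 6.5 / 44)
}

flat_config <- function() {
  analysis_config(block_len_frames = 200, n_blocks = 1,
                  camera_pixel_um = NULL, magnification = NULL,
                  pixel_size_um = 6.5 / 44)
}

test_that("a constant stack normalizes to one and is gain-invariant", {
  cfg <- flat_config()
  cell <- cell_mask(matrix(TRUE, 24, 24), cfg$pixel_size_um)
  seg <- prepare_spark_segment(make_flat_stack(100), cell, cfg)
  expect_true(all(abs(block_dff(seg, 1)) < 1e-12))
  set.seed(1)
  arr <- array(100 + rnorm(24 * 24 * 200, 0, 5)^2, c(24, 24, 200))
  s1 <- timelapse_stack(arr, pixel_size_um = cfg$pixel_size_um)
  s2 <- timelapse_stack(arr * 10, pixel_size_um = cfg$pixel_size_um)
  d1 <- block_dff(prepare_spark_segment(s1, cell, cfg), 1)
  d2 <- block_dff(prepare_spark_segment(s2, cell, cfg), 1)
  # cumulative-sum smoothing carries ~1e-11 cancellation error
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("the smoothing kernel conserves mass for an interior impulse", {
  cfg <- flat_config()
  arr <- array(0, c(24, 24, 200))
  arr[12, 12, 100] <- 1
  sm <- myospark:::box_smooth_3d(arr, cfg$smooth_kernel)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
})

test_that("a segment shorter than one block is rejected", {
  cfg <- flat_config()
  cell <- cell_mask(matrix(TRUE, 24, 24), cfg$pixel_size_um)
  short <- make_flat_stack(100, c(24L, 24L, 150L))
  expect_error(prepare_spark_segment(short, cell, cfg), "shorter")
})

test_that("characterization matches direct arithmetic on a constructed spark", {
  cfg <- flat_config()
  n <- 40L
  d <- c(n, n, 200L)
  px_um <- cfg$pixel_size_um
  dt_ms <- 1000 / 395
  # separable: Gaussian in space (FWHM 2 um), triangular in time
  sigma_px <- 2 / 2.3548 / px_um
  A <- 1
  g <- exp(-(outer((1:n - 20)^2, (1:n - 21)^2, "+")) / (2 * sigma_px^2))
  s_t <- c(rep(0, 79), seq(0, 1, length.out = 16)[-1],
           seq(1, 0, length.out = 16)[-1], rep(0, 91))
  dff <- array(0, d)
  for (t in which(s_t > 0)) dff[, , t] <- A * g * s_t[t]
  dffm <- matrix(dff, n * n, 200)
  tl <- 0.25
  vox <- which(dffm > tl)
  seg <- list(dims = d, block_len = 200L, n_blocks = 1L,
              frame_rate_hz = 395, pixel_size_um = px_um, config = cfg,
              valid = matrix(TRUE, n, n))
  class(seg) <- "spark_segment"
  ev <- characterize_spark(list(block = 1L, voxels = vox), seg, dffm)

  # oracle: direct formulas on the constructed arrays
  foot <- unique(((vox - 1) %% (n * n)) + 1)
  expect_equal(ev$area_px, length(foot))
  profile <- colMeans(dffm[foot, ]) + 1
  frames_on <- range(((vox - 1) %/% (n * n)) + 1)
  base <- mean(profile[-(frames_on[1]:frames_on[2])])
  amp <- (max(profile) - base) / base
  expect_equal(ev$amplitude, amp, tolerance = 1e-12)
  f50 <- base + (max(profile) - base) / 2
  above <- which(profile >= f50)
  expect_equal(ev$fdhm_ms, (max(above) - min(above)) * dt_ms,
               tolerance = 1e-12)
  # the mask-averaged amplitude is the footprint mean of the spatial profile
  expect_equal(amp, mean(g[foot]) * max(s_t) * A, tolerance = 0.02)
  # COM: symmetric Gaussian centred at (20, 21)
  expect_lt(abs(ev$com_y_px - 20), 0.05)
  expect_lt(abs(ev$com_x_px - 21), 0.05)
  # FWHM: pixels at or above f50 along the lines through the COM at peak
  peak_img <- matrix(dffm[, which.max(profile)], n, n) + 1
  expect_equal(ev$fwhm_x_um, sum(peak_img[20, ] >= f50) * px_um)
  expect_equal(ev$fwhm_y_um, sum(peak_img[, 21] >= f50) * px_um)
  expect_equal(ev$flags, "")
})

test_that("mass is the amplitude x mean FWHM x FDHM identity", {
  runs <- recovery_runs()
  all_sparks <- do.call(rbind, lapply(runs, `[[`, "sparks"))
  expect_gt(nrow(all_sparks), 20)
  expect_equal(all_sparks$mass_ms_um,
               all_sparks$amplitude *
                 (all_sparks$fwhm_x_um + all_sparks$fwhm_y_um) / 2 *
                 all_sparks$fdhm_ms,
               tolerance = 1e-12)
})

test_that("area and duration filters use the stated inclusive boundaries", {
  cfg <- analysis_config()
  template <- myospark:::empty_spark_table()[0, ]
  mk <- function(area, t_on, flags = "") {
    x <- template
    x[1, ] <- list(1L, 1L, as.integer(t_on), as.integer(area), 1, 5, 5,
                   0.5, 25, 2, 2, 25, 0, "epitubular", flags)
    x
  }
  expect_equal(nrow(filter_sparks(mk(49, 10), cfg)), 0)  # below 50 rejected
  expect_equal(nrow(filter_sparks(mk(50, 10), cfg)), 1)  # 50 retained
  expect_equal(nrow(filter_sparks(mk(60, 3), cfg)), 0)   # below 4 frames
  expect_equal(nrow(filter_sparks(mk(60, 4), cfg)), 1)
  expect_equal(nrow(filter_sparks(mk(500, 30, "unfinished"), cfg)), 0)
  expect_equal(nrow(filter_sparks(mk(500, 30, "boundary_truncated"), cfg)), 0)
})

test_that("one injected spark is recovered as exactly one event with a faithful COM", {
  spec <- phantom_spec(fov_px = c(96L, 96L), length_um = 12, width_um = 8,
                       unpaced_s = 500 / 395, paced_s = 0,
                       spark_rate_per_100um2_s = c(epitubular = 0,
                                                   paratubular = 0,
                                                   detubulated = 0),
                       detub_patches = 0L, n_nuclei = 0L, seed = 31)
  truth <- generate_phantom(spec)
  kin <- myospark:::.spark_kinetics(30)
  truth$sparks <- data.frame(
    id = 1L, category = "epitubular", com_row = 47.3, com_col = 49.6,
    onset_frame = 200L,
    peak_frame = 200L + round(kin$t_peak_ms * 395 / 1000),
    amplitude = 1.0, fwhm_um = 2.0, fdhm_ms = 30, truncated = FALSE)
  bundle <- render_recording(truth)
  cfg <- phantom_config(spec)
  cal <- subtract_background(bundle$calcium)
  cell <- segment_cell(cal)
  sp <- detect_sparks(cal, cell, truth$dnt, cfg)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$com_y_px - 47.3), 1)
  expect_lt(abs(sp$com_x_px - 49.6), 1)
  expect_lt(abs(sp$fdhm_ms - 30), 2 * 1000 / 395)
  expect_equal(sp$category, "epitubular")

  # detection output is invariant to a global gain (post background subtraction)
  cal3 <- cal
  cal3$intensities <- cal3$intensities * 3
  sp3 <- detect_sparks(cal3, cell, truth$dnt, cfg)
  expect_equal(sp3$com_x_px, sp$com_x_px, tolerance = 1e-9)
  expect_equal(sp3$amplitude, sp$amplitude, tolerance = 1e-9)
  expect_equal(sp3$mass_ms_um, sp$mass_ms_um, tolerance = 1e-9)
})

test_that("pure noise yields at most one false positive per block", {
  spec <- phantom_spec(fov_px = c(96L, 96L), length_um = 12, width_um = 8,
                       unpaced_s = 1000 / 395, paced_s = 0,
                       spark_rate_per_100um2_s = c(epitubular = 0,
                                                   paratubular = 0,
                                                   detubulated = 0),
                       detub_patches = 0L, n_nuclei = 0L, seed = 57)
  truth <- generate_phantom(spec)
  bundle <- render_recording(truth)
  cfg <- phantom_config(spec)
  cal <- subtract_background(bundle$calcium)
  cell <- segment_cell(cal)
  sp <- detect_sparks(cal, cell, NULL, cfg)
  expect_lte(nrow(sp), cfg$n_blocks)
})

test_that("a spark straddling a block boundary is flagged boundary-truncated", {
  spec <- phantom_spec(fov_px = c(96L, 96L), length_um = 12, width_um = 8,
                       unpaced_s = 1000 / 395, paced_s = 0,
                       spark_rate_per_100um2_s = c(epitubular = 0,
                                                   paratubular = 0,
                                                   detubulated = 0),
                       detub_patches = 0L, n_nuclei = 0L, seed = 33)
  truth <- generate_phantom(spec)
  kin <- myospark:::.spark_kinetics(30)
  truth$sparks <- data.frame(
    id = 1L, category = "epitubular", com_row = 47, com_col = 49,
    onset_frame = 495L,   # block boundary at frame 500
    peak_frame = 495L + round(kin$t_peak_ms * 395 / 1000),
    amplitude = 1.0, fwhm_um = 2.0, fdhm_ms = 30, truncated = FALSE)
  bundle <- render_recording(truth)
  cfg <- phantom_config(spec)
  cal <- subtract_background(bundle$calcium)
  cell <- segment_cell(cal)
  seg <- prepare_spark_segment(cal, cell, cfg)
  det <- detect_spark_candidates(seg)
  expect_gte(length(det$components), 1)
  evs <- do.call(rbind, lapply(seq_along(det$components), function(i) {
    cp <- det$components[[i]]
    characterize_spark(cp, seg, block_dff(seg, cp$block, det$f0_2), id = i)
  }))
  expect_true(any(grepl("boundary_truncated", evs$flags)))
  expect_equal(nrow(filter_sparks(evs, cfg)), 0)
})

test_that("the second pass never inflates the baseline under pass-1 sparks", {
  runs <- recovery_runs()
  r <- runs[[2]]
  cfg <- phantom_config(r$spec)
  cal <- subtract_background(render_recording(r$truth)$calcium)
  seg <- prepare_spark_segment(cal, r$cell, cfg)
  det <- detect_spark_candidates(seg)
  expect_gt(length(det$preliminary), 0)
  npx <- seg$dims[1] * seg$dims[2]
  for (cp in det$preliminary) {
    pixels <- unique(((cp$voxels - 1) %% npx) + 1)
    delta <- det$f0_2[pixels, cp$block] - seg$f0[pixels, cp$block]
    expect_lt(mean(delta), 0)
    expect_lt(max(delta), 0.01 * mean(seg$f0[pixels, cp$block]))
  }
})

test_that("spark COMs sit closer to tubules than random pixels (sign test)", {
  runs <- recovery_runs()
  closer <- vapply(runs, function(r) {
    if (is.null(r$sparks) || nrow(r$sparks) == 0) return(NA)
    mean(r$sparks$dnt_px, na.rm = TRUE) <
      mean_random_dnt(r$truth$dnt, r$truth$cell)
  }, logical(1))
  closer <- closer[!is.na(closer)]
  expect_gte(sum(closer), ceiling(0.75 * length(closer)))
})

test_that("spark rates are per category area and time; zero-area categories are NA", {
  cfg <- analysis_config()
  cell <- cell_mask(matrix(TRUE, 60, 60), 1)  # 1 um pixels for round numbers
  dnt <- make_dnt(matrix(0, 60, 60))          # all epitubular
  dnt$dnt_px[, 31:60] <- 3                    # half paratubular
  dnt$category <- matrix(dnt_category(dnt$dnt_px, 5), 60, 60)
  template <- myospark:::empty_spark_table()[0, ]
  sparks <- do.call(rbind, replicate(10, {
    x <- template
    x[1, ] <- list(1L, 1L, 10L, 60L, 1.3, 5, 5, 0.5, 25, 2, 2, 25, 0,
                   "epitubular", "")
    x
  }, simplify = FALSE))
  rates <- compute_spark_rates(sparks, dnt, cell, duration_s = 10, cfg)
  epi <- rates[rates$category == "epitubular", ]
  # 10 sparks over 1800 um2 for 10 s -> 10 / 18 / 10
  expect_equal(epi$rate_per_100um2_s, 10 / (1800 / 100) / 10)
  expect_equal(epi$fraction, 1)
  expect_equal(rates$n_sparks[rates$category == "paratubular"], 0L)
  expect_equal(rates$rate_per_100um2_s[rates$category == "paratubular"], 0)
  expect_true(is.na(rates$rate_per_100um2_s[rates$category == "detubulated"]))
})

test_that("generator rate ratios are recovered from pooled truth draws", {
  # aggregate spark counts across phantoms; epitubular rate is set 2.5x the
  # paratubular rate
  counts <- c(epitubular = 0, paratubular = 0)
  areas <- c(epitubular = 0, paratubular = 0)
  secs <- 0
  for (seed in 1:12) {
    spec <- phantom_spec(unpaced_s = 10, paced_s = 0, seed = seed,
                         spark_rate_per_100um2_s = c(epitubular = 2,
                                                     paratubular = 0.8,
                                                     detubulated = 0.1))
    truth <- generate_phantom(spec)
    for (k in names(counts)) {
      counts[k] <- counts[k] + sum(truth$sparks$category == k)
      areas[k] <- areas[k] + sum(truth$dnt$category == k, na.rm = TRUE) *
        spec$pixel_size_um^2
    }
    secs <- secs + spec$unpaced_s
  }
  expect_gt(sum(counts), 200)
  rate_ratio <- (counts["epitubular"] / areas["epitubular"]) /
    (counts["paratubular"] / areas["paratubular"])
  se_log <- sqrt(1 / counts["epitubular"] + 1 / counts["paratubular"])
  expect_lt(abs(log(rate_ratio / 2.5)), 3 * se_log)
})
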