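tiny_spec <- function(...) {
  phantom_spec(fov_px = c(64L, 96L), length_um = 12, width_um = 6,
               unpaced_s = 100 / 395, paced_s = 0, n_nuclei = 0L,
               detub_patches = 0L, ...)
}

test_that("the same seed reproduces bit-identical truth and movies", {
  s <- tiny_spec(seed = 9)
  t1 <- generate_phantom(s); t2 <- generate_phantom(s)
  expect_identical(t1$tubules$mask, t2$tubules$mask)
  expect_identical(t1$sparks, t2$sparks)
  expect_identical(t1$t50_ms, t2$t50_ms)
  b1 <- render_recording(t1); b2 <- render_recording(t2)
  expect_identical(b1$calcium$intensities, b2$calcium$intensities)
  expect_identical(b1$membrane$intensities, b2$membrane$intensities)
})

test_that("the tubule lattice rasterizes at the whole-pixel period", {
  expect_equal(round(2 / (6.5 / 44)), 14)
  s <- tiny_spec(seed = 9, longitudinal_fraction = 0)
  t <- generate_phantom(s)
  # stripe onsets along the central row repeat every 14 px
  row <- t$tubules$mask[32, ]
  onsets <- which(diff(c(FALSE, row)) == 1)
  gaps <- diff(onsets)
  # the outermost stripes can be clipped by the ellipse boundary
  if (length(gaps) > 2) gaps <- gaps[-c(1, length(gaps))]
  expect_true(all(gaps == 14))
})

test_that("without detubulated patches (or nuclei) almost no detubulated area remains", {
  t <- generate_phantom(tiny_spec(seed = 4))
  # only slivers at the tapering cell tips, where the ellipse outlives the
  # outermost stripe, may exceed the 5 px bound
  detub <- sum(t$dnt$category == "detubulated", na.rm = TRUE)
  expect_lt(detub / t$cell$area_px, 0.02)
})

test_that("a cell larger than the field of view is rejected", {
  expect_error(phantom_spec(fov_px = c(64L, 96L), length_um = 50,
                            width_um = 6), "larger than the field of view")
})

test_that("the half-rise oracle has the known closed forms", {
  # linear ramp: exactly half the rise time
  s_ramp <- tiny_spec(transient_shape = "ramp", ramp_rise_ms = 24,
                      base_delay_ms = 0, seed = 1)
  expect_equal(analytic_t50_oracle(s_ramp), 12)
  expect_equal(analytic_t50_oracle(s_ramp, delay_ms = 7), 19)
  # exponential rise with slow decay: tau * ln 2
  s_exp <- tiny_spec(tau_rise_ms = 10, tau_decay_ms = 1e7, seed = 1)
  expect_equal(analytic_t50_oracle(s_exp), 10 * log(2), tolerance = 1e-3)
})

test_that("the half-rise oracle agrees with a dense-grid search", {
  for (seed in 1:6) {
    set.seed(seed)
    s <- tiny_spec(tau_rise_ms = runif(1, 5, 30),
                   tau_decay_ms = runif(1, 100, 800), seed = seed)
    t_grid <- seq(0, 200, by = 1e-4)
    f <- (1 - exp(-t_grid / s$tau_rise_ms)) * exp(-t_grid / s$tau_decay_ms)
    rise <- t_grid[t_grid <= t_grid[which.max(f)]]
    target <- max(f) / 2
    grid_t50 <- rise[which.min(abs(f[seq_along(rise)] - target))]
    expect_lt(abs(analytic_t50_oracle(s) - grid_t50), 1e-3)
  }
})

test_that("the truth T50 field is the delay field plus the half-rise", {
  s <- tiny_spec(seed = 5, nuclear_extra_delay_ms = 0, end_offset_ms = 0)
  t <- generate_phantom(s)
  hr <- analytic_t50_oracle(s)
  expect_equal(t$t50_ms[t$cell$mask], t$delay_ms[t$cell$mask] + hr)
  expect_true(all(is.na(t$t50_ms[!t$cell$mask])))
})

test_that("rendered spark counts follow the configured rates within binomial error", {
  total <- 0; expected <- 0
  for (seed in 1:10) {
    s <- phantom_spec(unpaced_s = 6, paced_s = 0, seed = seed)
    t <- generate_phantom(s)
    total <- total + nrow(t$sparks)
    for (k in names(s$spark_rate_per_100um2_s)) {
      area <- sum(t$dnt$category == k, na.rm = TRUE) * s$pixel_size_um^2
      expected <- expected + s$spark_rate_per_100um2_s[[k]] * area / 100 * 6
    }
  }
  expect_lt(abs(total - expected), 4 * sqrt(expected))
})

test_that("spaced placement keeps events isolated in space-time", {
  s <- phantom_spec(unpaced_s = 6, paced_s = 0, seed = 3,
                    spark_placement = "spaced",
                    spark_rate_per_100um2_s = c(epitubular = 2,
                                                paratubular = 1,
                                                detubulated = 0.2))
  t <- generate_phantom(s)
  sp <- t$sparks
  expect_gt(nrow(sp), 3)
  dt_ms <- 1000 / s$frame_rate_hz
  for (i in seq_len(nrow(sp) - 1)) {
    for (j in (i + 1):nrow(sp)) {
      d_px <- sqrt((sp$com_row[i] - sp$com_row[j])^2 +
                     (sp$com_col[i] - sp$com_col[j])^2)
      d_ms <- abs(sp$onset_frame[i] - sp$onset_frame[j]) * dt_ms
      close_px <- d_px < 1.2 * (sp$fwhm_um[i] + sp$fwhm_um[j]) /
        s$pixel_size_um
      close_ms <- d_ms < 2 * (sp$fdhm_ms[i] + sp$fdhm_ms[j])
      expect_false(close_px && close_ms)
    }
  }
})

test_that("the CLI simulates and analyses a phantom end to end", {
  d <- withr::local_tempdir()
  cfg_file <- file.path(d, "phantom.yaml")
  yaml::write_yaml(list(fov_px = c(64L, 96L), length_um = 12, width_um = 6,
                        unpaced_s = 100 / 395, paced_s = 0,
                        n_nuclei = 0L, detub_patches = 0L), cfg_file)
  myospark_cli(c("simulate", "--config", cfg_file, "--seed", "9",
                 "--out", d))
  expect_true(file.exists(file.path(d, "calcium.tif")))
  expect_true(file.exists(file.path(d, "truth_sparks.csv")))
  acfg <- file.path(d, "analysis.yaml")
  yaml::write_yaml(list(block_len_frames = 100, n_blocks = 1,
                        pixel_size_um = 6.5 / 44,
                        channel_scale_ratio = 1), acfg)
  out <- file.path(d, "results")
  myospark_cli(c("sparks", "--calcium", file.path(d, "calcium.tif"),
                 "--membrane", file.path(d, "membrane.tif"),
                 "--config", acfg, "--out", out))
  expect_true(file.exists(file.path(out, "sparks.csv")))
})
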