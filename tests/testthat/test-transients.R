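# A hand-built transient window: flat baseline, linear rise to a plateau.
make_ramp_window <- function(edge_frame = 21L, rise_frames = 10L,
                             f0 = 100, peak = 200, nt = 60L, npx = 6L,
                             delay_frames = 0L) {
  dt_ms <- 1000 / 395
  trace <- rep(f0, nt)
  r0 <- edge_frame + delay_frames
  ramp <- seq_len(rise_frames)
  trace[r0 + ramp] <- f0 + (peak - f0) * ramp / rise_frames
  trace[(r0 + rise_frames + 1):nt] <- peak
  data <- array(rep(trace, each = npx * npx), c(npx, npx, nt))
  structure(list(
    data = data, frame_offset = 0L,
    edge_time_ms = (edge_frame - 1) * dt_ms,
    edge_frame = edge_frame,
    peak_frame = r0 + rise_frames + 5L,
    time_ms = (seq_len(nt) - 1) * dt_ms,
    baseline_map = matrix(f0, npx, npx),
    peak_map = matrix(peak, npx, npx),
    dff_peak_map = matrix((peak - f0) / f0, npx, npx),
    frame_rate_hz = 395), class = "transient_window")
}

test_that("a linear ramp from baseline crosses half-maximum at its midpoint", {
  w <- make_ramp_window()
  cell <- cell_mask(matrix(TRUE, 6, 6), 0.1477)
  t50 <- compute_t50_map(w, cell)
  expect_equal(t50[3, 3], 5 * 1000 / 395, tolerance = 1e-9)  # 12.66 ms
  expect_true(all(abs(t50 - t50[1, 1]) < 1e-9))
})

test_that("T50 is equivariant under temporal shifts and invariant under gain", {
  cell <- cell_mask(matrix(TRUE, 6, 6), 0.1477)
  base <- compute_t50_map(make_ramp_window(), cell)
  for (k in c(2L, 7L)) {
    shifted <- compute_t50_map(make_ramp_window(delay_frames = k), cell)
    expect_equal(shifted - base, matrix(k * 1000 / 395, 6, 6),
                 tolerance = 1e-9)
  }
  w2 <- make_ramp_window()
  w2$data <- w2$data * 4
  w2$baseline_map <- w2$baseline_map * 4
  w2$peak_map <- w2$peak_map * 4
  expect_equal(compute_t50_map(w2, cell), base, tolerance = 1e-9)
})

test_that("pixels without a rise or crossing are undefined", {
  w <- make_ramp_window()
  # peak below baseline at one pixel
  w$peak_map[2, 2] <- 50
  # already above F50 at the stimulus at another
  w$data[4, 4, ] <- 500
  cell <- cell_mask(matrix(TRUE, 6, 6), 0.1477)
  t50 <- compute_t50_map(w, cell)
  expect_true(is.na(t50[2, 2]))
  expect_true(is.na(t50[4, 4]))
  expect_false(is.na(t50[3, 3]))
})

test_that("three consecutive transients are located with the pacing period", {
  r <- t50_nuclear_run()
  expect_length(r$windows, 3)
  peaks_ms <- vapply(r$windows, function(w) {
    w$time_ms[w$peak_frame]
  }, numeric(1))
  gaps <- diff(peaks_ms) / 1000
  expect_true(all(abs(gaps - 2) < 0.05))
  for (w in r$windows) {
    expect_equal(w$data_dim[3], 525)
    expect_lt(w$edge_time_ms, w$time_ms[w$peak_frame])
    # baseline window precedes the stimulus edge
    expect_gte(w$edge_frame - 50, 1)
  }
})

test_that("aggregation takes the pixel-wise mean and SD where all maps are defined", {
  m1 <- matrix(10, 4, 4); m2 <- matrix(20, 4, 4); m3 <- matrix(30, 4, 4)
  m1[1, 1] <- NA
  agg <- aggregate_t50_maps(list(m1, m2, m3))
  expect_equal(agg$mean[2, 2], 20)
  expect_equal(agg$sd[2, 2], 10)
  expect_true(is.na(agg$mean[1, 1]))
  expect_false(agg$valid[1, 1])
  same <- aggregate_t50_maps(list(m2, m2, m2))
  expect_true(all(same$sd[same$valid] == 0))
  expect_error(aggregate_t50_maps(list(m1)), "2")
})

test_that("uniform maps summarize to equal medians, zero deltas and zero IQR", {
  cellm <- matrix(FALSE, 30, 80)
  cellm[5:25, 10:70] <- TRUE
  cell <- cell_mask(cellm, 0.1477)
  m <- matrix(NA_real_, 30, 80)
  m[cellm] <- 30
  nuc <- structure(list(mask = matrix(FALSE, 30, 80), n_nuclei = 1L),
                   class = "nucleus_mask")
  nuc$mask[12:18, 35:45] <- TRUE
  s <- summarize_regions(m, cell, nuc)
  expect_equal(s$median_cell_ms, 30)
  expect_equal(s$median_nucleus_ms, 30)
  expect_equal(s$delta_nucleus_ms, 0)
  expect_equal(s$delta_central_outer_ms, 0)
  expect_equal(s$dyssynchrony_iqr_ms, 0)
  # nuclear pixels never leak into the exonuclear median (disjointness)
  m2 <- m; m2[nuc$mask] <- 1000
  s2 <- summarize_regions(m2, cell, nuc)
  expect_equal(s2$median_exonuclear_ms, 30)
  expect_equal(s2$median_nucleus_ms, 1000)
  # without nuclei the nuclear fields are missing, not zero
  s3 <- summarize_regions(m, cell, NULL)
  expect_true(is.na(s3$median_nucleus_ms))
  expect_true(is.na(s3$delta_nucleus_ms))
})

test_that("perfectly linear T50-DNT data fit with the exact slope", {
  set.seed(5)
  dnt_px <- matrix(sample(0:12, 900, replace = TRUE), 30, 30)
  dnt <- make_dnt(dnt_px)
  t50 <- 2 * dnt_px + 20
  # lm warns about an essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_t50_vs_dnt(t50, dnt))
  expect_equal(fit$slope_ms_per_px, c(2, 2), tolerance = 1e-9)
  expect_equal(fit$intercept_ms, c(20, 20), tolerance = 1e-8)
  expect_true(all(fit$ci_hi - fit$ci_lo < 1e-6))
  expect_true(all(fit$ci_lo <= fit$slope_ms_per_px &
                    fit$slope_ms_per_px <= fit$ci_hi))
})

test_that("under a permutation null the slope CI covers zero at its nominal rate", {
  set.seed(17)
  dnt_px <- matrix(sample(0:12, 400, replace = TRUE), 20, 20)
  dnt <- make_dnt(dnt_px)
  covered <- logical(50)
  for (i in seq_len(50)) {
    t50 <- matrix(rnorm(400, 30, 2), 20, 20)  # independent of DNT
    fit <- fit_t50_vs_dnt(t50, dnt)
    row <- fit[fit$class == "tubulated", ]
    covered[i] <- row$ci_lo <= 0 && 0 <= row$ci_hi
  }
  expect_gte(mean(covered), 0.9)
})

test_that("degenerate DNT variance or tiny samples yield NA fits", {
  dnt <- make_dnt(matrix(3, 10, 10))
  fit <- fit_t50_vs_dnt(matrix(30, 10, 10), dnt)
  expect_true(is.na(fit$slope_ms_per_px[fit$class == "tubulated"]))
  expect_true(is.na(fit$slope_ms_per_px[fit$class == "detubulated"]))
})
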