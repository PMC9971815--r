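# Shared fixtures, generated in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Brute-force nearest-tubule distance: the independent oracle for the
# Euclidean distance transform.
brute_force_dnt <- function(tubule_mask, cell_mask) {
  idx <- which(tubule_mask & cell_mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(cell_mask), ncol(cell_mask))
  for (p in which(cell_mask)) {
    r <- ((p - 1) %% nrow(cell_mask)) + 1
    c <- ((p - 1) %/% nrow(cell_mask)) + 1
    out[r, c] <- if (nrow(idx)) {
      sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
    } else Inf
  }
  out
}

# ---- spark-recovery benchmark -----------------------------------------------
# A small myocyte with isolated ("spaced") sparks at rates raised for
# statistical power at desk scale; one ~2.5 s unpaced recording per seed.
recovery_spec <- function(seed) {
  phantom_spec(fov_px = c(112L, 112L), length_um = 15, width_um = 9.5,
               unpaced_s = 1000 / 395, paced_s = 0,
               spark_rate_per_100um2_s = c(epitubular = 3, paratubular = 1.2,
                                           detubulated = 0.5),
               detub_patches = 1L, n_nuclei = 1L,
               spark_placement = "spaced", seed = seed)
}

run_recovery_seed <- function(seed) {
  spec <- recovery_spec(seed)
  truth <- generate_phantom(spec)
  bundle <- render_recording(truth)
  cfg <- phantom_config(spec)
  cal <- subtract_background(bundle$calcium)
  cell <- segment_cell(cal)
  sparks <- detect_sparks(cal, cell, truth$dnt, cfg)
  # distance of each truth COM from the cell border, for the
  # fully-visible-event recall denominator
  dedge <- EBImage::imageData(
    EBImage::distmap(EBImage::Image(truth$cell$mask * 1)))
  tr <- truth$sparks
  tr$edge_dist_px <- if (nrow(tr)) {
    dedge[cbind(pmin(pmax(round(tr$com_row), 1), nrow(dedge)),
                pmin(pmax(round(tr$com_col), 1), ncol(dedge)))]
  } else numeric(0)
  list(spec = spec, truth = truth, cell = cell, sparks = sparks, tr = tr)
}

recovery_runs <- function(n_seeds = 20) {
  cached(sprintf("recovery_%d", n_seeds), lapply(seq_len(n_seeds) + 100L,
                                                 run_recovery_seed))
}

# Recall over fully-visible, untruncated truth sparks (COM at least
# `margin_um` inside the cell border), matched within 2 px and 2 frames;
# precision of all detections against any truth event with a relaxed
# association window (edge-clipped events have displaced apparent COMs).
recovery_stats <- function(runs, margin_um = 1.5) {
  n_truth <- 0L; n_hit <- 0L; n_det <- 0L; n_assoc <- 0L
  for (r in runs) {
    margin_px <- margin_um / r$spec$pixel_size_um
    tr <- r$tr
    sp <- r$sparks
    n_det <- n_det + nrow(sp)
    if (!nrow(tr)) next
    dmat <- sqrt(outer(sp$com_y_px, tr$com_row, "-")^2 +
                   outer(sp$com_x_px, tr$com_col, "-")^2)
    fmat <- abs(outer(sp$peak_frame, tr$peak_frame, "-"))
    bench <- !tr$truncated & tr$edge_dist_px >= margin_px
    n_truth <- n_truth + sum(bench)
    if (nrow(sp)) {
      strict <- dmat <= 2 & fmat <= 2
      n_hit <- n_hit + sum(apply(strict[, bench, drop = FALSE], 2, any))
      loose <- dmat <= 6 & fmat <= 5
      n_assoc <- n_assoc + sum(apply(loose, 1, any))
    }
  }
  list(recall = n_hit / n_truth, precision = n_assoc / n_det,
       n_truth = n_truth, n_det = n_det)
}

# ---- paced transient fixtures ----------------------------------------------
paced_base_args <- function() {
  list(fov_px = c(80L, 160L), length_um = 21, width_um = 9,
       paced_s = 8, unpaced_s = 0)
}

run_paced <- function(spec) {
  truth <- generate_phantom(spec)
  bundle <- render_recording(truth, noise = spec$noise_sd_dn > 0,
                             channels = "calcium")
  cfg <- phantom_config(spec, block_len_frames = 100)
  cal <- subtract_background(bundle$calcium)
  pacing <- bundle$pacing
  rm(bundle); gc(verbose = FALSE)
  cell <- segment_cell(cal)
  wins <- locate_transients(cal, pacing, cell, cfg, start_periods = 0)
  rm(cal); gc(verbose = FALSE)
  maps <- lapply(wins, compute_t50_map, cell = cell)
  agg <- aggregate_t50_maps(maps)
  # keep window metadata but free the cropped movies
  wins <- lapply(wins, function(w) {
    w$data_dim <- dim(w$data)
    w$data <- NULL
    w
  })
  gc(verbose = FALSE)
  list(spec = spec, truth = truth, cell = cell, windows = wins,
       maps = maps, agg = agg)
}

# Noiseless phantom with a spatially uniform onset delay: isolates the
# temporal accuracy of the T50 estimator against the analytic oracle.
t50_uniform_run <- function() {
  cached("t50_uniform", {
    args <- c(paced_base_args(),
              list(noise_sd_dn = 0, nuclear_extra_delay_ms = 0,
                   end_offset_ms = 0, n_nuclei = 0L, seed = 3))
    run_paced(do.call(phantom_spec, args))
  })
}

# Noisy phantom with only the nuclear delay field active.
t50_nuclear_run <- function() {
  cached("t50_nuclear", {
    args <- c(paced_base_args(),
              list(end_offset_ms = 0, nuclear_extra_delay_ms = 3.5,
                   n_nuclei = 1L, seed = 11))
    run_paced(do.call(phantom_spec, args))
  })
}

# Noisy phantom with only the end-vs-centre offset active.
t50_ends_run <- function() {
  cached("t50_ends", {
    args <- c(paced_base_args(),
              list(end_offset_ms = -2, nuclear_extra_delay_ms = 0,
                   n_nuclei = 0L, seed = 12))
    run_paced(do.call(phantom_spec, args))
  })
}

# ---- small structural phantom (no rendering of long movies) ----------------
structure_run <- function() {
  cached("structure", {
    spec <- phantom_spec(fov_px = c(96L, 160L), length_um = 21, width_um = 10,
                         unpaced_s = 60 / 395, paced_s = 0, noise_sd_dn = 8,
                         seed = 5)
    truth <- generate_phantom(spec)
    bundle <- render_recording(truth)
    cfg <- phantom_config(spec, block_len_frames = 60)
    cal <- subtract_background(bundle$calcium)
    cell <- segment_cell(cal)
    mem <- subtract_background(bundle$membrane)
    tub <- extract_tubule_mask(mem, cell, cfg)
    list(spec = spec, truth = truth, bundle = bundle, cfg = cfg,
         cal = cal, cell = cell, mem = mem, tub = tub)
  })
}

# A minimal dnt_map object for arithmetic checks.
make_dnt <- function(dnt_px, max_px = 5) {
  structure(list(dnt_px = dnt_px,
                 category = matrix(dnt_category(dnt_px, max_px),
                                   nrow(dnt_px), ncol(dnt_px)),
                 paratubular_max_px = max_px,
                 paratubular_max_um = max_px * 6.5 / 44),
            class = "dnt_map")
}
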