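#' Run the full analysis pipeline on a recording
#'
#' Pre-processing (co-registration, background subtraction, cell
#' segmentation), structure extraction (tubule mask, DNT map, optional
#' nuclei), spark detection with DNT-resolved rates and — when the bundle is
#' paced — the pixel-wise T50 analysis with regional summaries and the
#' T50-vs-DNT fits. Stages that cannot run on a given recording (e.g. too
#' few frames for the spark segment, or an unpaced bundle for the transient
#' stages) are skipped with a message and return `NULL` in the result.
#'
#' @param bundle A [recording_bundle()].
#' @param config An [analysis_config()].
#' @param nuclei_polygons Optional nucleus outlines (list of
#'   `list(x =, y =)`), e.g. from [read_nuclei_polygons()].
#' @param start_periods Passed to [locate_transients()].
#' @return List with `cell`, `tubules`, `nuclei`, `dnt`, `sparks`,
#'   `spark_rates`, `t50`, `regions`, `fit` and the registration result.
#' @export
analyze_recording <- function(bundle, config = analysis_config(),
                              nuclei_polygons = list(),
                              start_periods = 2) {
  reg <- coregister_channels(bundle$calcium, bundle$membrane,
                             config = config)
  calcium <- subtract_background(reg$calcium)
  membrane <- subtract_background(reg$membrane)
  cell <- segment_cell(calcium)
  tubules <- extract_tubule_mask(membrane, cell, config)
  dnt <- compute_dnt_map(tubules, cell, config)
  nuclei <- rasterize_nuclei(nuclei_polygons, cell)

  sparks <- NULL; spark_rates <- NULL
  res <- tryCatch({
    sp <- detect_sparks(calcium, cell, dnt, config)
    list(sp = sp,
         rates = compute_spark_rates(sp, dnt, cell,
                                     attr(sp, "segment_duration_s"), config))
  }, error = function(e) {
    message("spark stage skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(res)) {
    sparks <- res$sp
    spark_rates <- res$rates
  }

  t50 <- NULL; regions <- NULL; fit <- NULL
  if (!bundle$unpaced) {
    tr <- tryCatch({
      wins <- locate_transients(calcium, bundle$pacing, cell, config,
                                start_periods = start_periods)
      maps <- lapply(wins, compute_t50_map, cell = cell)
      agg <- aggregate_t50_maps(maps)
      list(t50 = agg,
           regions = summarize_regions(agg, cell, nuclei),
           fit = fit_t50_vs_dnt(agg, dnt))
    }, error = function(e) {
      message("transient stage skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(tr)) {
      t50 <- tr$t50; regions <- tr$regions; fit <- tr$fit
    }
  } else {
    message("unpaced bundle: transient stages not run")
  }
  list(cell = cell, tubules = tubules, nuclei = nuclei, dnt = dnt,
       sparks = sparks, spark_rates = spark_rates,
       t50 = t50, regions = regions, fit = fit,
       registration = reg[c("shift", "correlation")])
}
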