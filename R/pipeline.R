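# Pipeline orchestration and category reporting.
#
# run_pipeline() executes the full workflow — vegetation (BFI), reach
# segmentation, terrain, hydrology, the two fuzzy-inference stages and the
# capacity constraints — and optionally the observation/validation and
# dam-number prediction stages, recording a manifest of configuration,
# seeds, versions and per-stage timings.

#' Summarise a per-category absolutes table
#'
#' Takes category-level absolute quantities and recomputes the percentage
#' columns and the "All" row. Display rounding follows the reporting
#' conventions: lengths 2 d.p., percentages 2 d.p.
#' @param tbl data.frame with columns `category`, `channel_km`, `active_km`,
#'   `observed_dams`, and optionally `predicted_dams`.
#' @param aoi area-of-interest label for the output rows.
#' @return data.frame with percentage columns and a final "All" row.
#' @export
summarize_category_table <- function(tbl, aoi = "AOI") {
  stopifnot(all(c("category", "channel_km", "active_km", "observed_dams") %in% names(tbl)))
  if (nrow(tbl) == 0L) stop("empty category table")
  pct <- function(x) {
    tot <- sum(x)
    if (tot == 0) rep(0, length(x)) else 100 * x / tot
  }
  out <- data.frame(
    aoi = aoi, category = as.character(tbl$category),
    channel_km = round(tbl$channel_km, 2),
    network_pct = round(pct(tbl$channel_km), 2),
    active_km = round(tbl$active_km, 2),
    active_pct = round(pct(tbl$active_km), 2),
    observed_dams = tbl$observed_dams,
    observed_dams_pct = round(pct(tbl$observed_dams), 2),
    stringsAsFactors = FALSE)
  if ("predicted_dams" %in% names(tbl)) {
    out$predicted_dams <- round(tbl$predicted_dams, 2)
    out$predicted_pct <- round(pct(tbl$predicted_dams), 2)
  }
  all_row <- data.frame(
    aoi = aoi, category = "All",
    channel_km = round(sum(tbl$channel_km), 2), network_pct = 100,
    active_km = round(sum(tbl$active_km), 2), active_pct = 100,
    observed_dams = sum(tbl$observed_dams),
    observed_dams_pct = 100, stringsAsFactors = FALSE)
  if ("predicted_dams" %in% names(tbl)) {
    all_row$predicted_dams <- round(sum(tbl$predicted_dams), 2)
    all_row$predicted_pct <- 100
  }
  rbind(out, all_row)
}

#' Aggregate reach results by capacity category
#'
#' Builds the per-category summary (channel length, active length, observed
#' and predicted dams, with percentage shares and an "All" row) from reach
#' attributes.
#' @param reaches data.frame with `category`, `length_m`, `is_active`,
#'   `observed_dams`.
#' @param predictions optional per-reach expected dams (same order).
#' @param aoi area-of-interest label.
#' @return summary data.frame (one row per category plus "All").
#' @export
aggregate_by_category <- function(reaches, predictions = NULL, aoi = "AOI") {
  if (nrow(reaches) == 0L) stop("empty reach set")
  cats <- levels(factor(reaches$category))
  f <- factor(reaches$category, levels = cats)
  tbl <- data.frame(
    category = cats,
    channel_km = as.numeric(tapply(reaches$length_m, f, sum, default = 0)) / 1000,
    active_km = as.numeric(tapply(reaches$length_m * reaches$is_active, f, sum,
                                  default = 0)) / 1000,
    observed_dams = as.integer(tapply(reaches$observed_dams, f, sum, default = 0)),
    stringsAsFactors = FALSE)
  if (!is.null(predictions))
    tbl$predicted_dams <- as.numeric(tapply(predictions, f, sum, default = 0))
  summarize_category_table(tbl, aoi = aoi)
}

#' Run the full dam-capacity pipeline on a synthetic scenario
#'
#' Stages run in workflow order: vegetation (landcover to BFI), reach
#' segmentation and widths, terrain (burning, routing, slope, order),
#' hydrology (rating curves, stream power), the vegetation and combined
#' fuzzy-inference stages, and the capacity constraints. With
#' `simulate = TRUE` the scenario's observation model is simulated, points
#' snapped, activity flagged, and the Bayesian validation and ZINB dam-number
#' prediction stages run too.
#' @param scenario a `catchment_scenario`, or a list/YAML path with an
#'   element `scenario` of arguments for [catchment_scenario()].
#' @param simulate simulate observations and run validation/prediction.
#' @param bootstrap_reps bootstrap replicates for prediction intervals.
#' @param output_dir optional directory; when given, writes the reach layer
#'   (GeoJSON), BFI grid (ASCII grid), summary tables (CSV) and manifest
#'   (JSON).
#' @param acc_threshold_cells accumulation threshold for the raster stream
#'   (`NULL` calibrates a per-head threshold from the flow accumulation at
#'   each channel head; see [strahler_with_correction()]).
#' @return list with `reaches` (attribute table + geometry), `bfi`,
#'   `ratings`, `validation`, `prediction`, `summary`, `manifest`.
#' @export
run_pipeline <- function(scenario, simulate = TRUE, bootstrap_reps = 200,
                         output_dir = NULL, acc_threshold_cells = NULL) {
  if (is.character(scenario)) scenario <- yaml::read_yaml(scenario)
  if (!inherits(scenario, "catchment_scenario")) {
    if (is.null(scenario$scenario))
      stop("config must be a catchment_scenario or carry a 'scenario' element")
    scenario <- do.call(catchment_scenario, scenario$scenario)
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop(name, " stage failed: ", conditionMessage(e), call. = FALSE))
    tick(name)
    out
  }

  catchment <- stage("terrain_generation", generate_terrain(scenario))
  landcover <- stage("landcover_generation", generate_landcover(scenario, catchment))

  bfi <- stage("vegetation", {
    tabs <- default_suitability()
    ext <- c(0, 0, raster_ncol(catchment$dtm) * catchment$dtm$cellsize,
             raster_nrow(catchment$dtm) * catchment$dtm$cellsize)
    suit <- list(
      reclassify_source(landcover$os_vector, tabs$os_vector),
      reclassify_source(landcover$wlff_lines, tabs$wlff_lines),
      reclassify_source(landcover$lcm_raster, tabs$lcm_raster),
      reclassify_source(landcover$tcd_percent, tabs$tcd_percent))
    grids <- rasterize_and_align(suit, cellsize = 5, extent = ext)
    composite_bfi(grids, priority = 1)
  })

  reaches <- stage("reaches", {
    rch <- segment_network(catchment$network)
    w <- mean_bankfull_width(rch, catchment$channels)
    rch$width_m <- as.numeric(w)
    rch
  })

  fg <- NULL
  reaches <- stage("terrain", {
    burned <- burn_dtm(catchment$dtm, catchment$network)
    fg <- flow_accumulation(burned)
    reaches$slope <- reach_slope(reaches, catchment$dtm)
    reaches$contrib_area_km2 <- contributing_area(reaches, fg)
    so <- strahler_with_correction(fg, reaches, catchment$network,
                                   threshold_cells = acc_threshold_cells)
    reaches$strahler_order <- so$reach_order
    reaches
  })

  ratings <- NULL
  reaches <- stage("hydrology", {
    gf <- generate_flows(scenario, catchment, fg = fg)
    if (is.null(gf$flows) || !nrow(gf$flows))
      stop("missing input: gauge flow records")
    ratings <- fit_gauge_ratings(gf$flows, gf$gauges)
    q2 <- reach_discharge(ratings$q2, reaches$contrib_area_km2)
    q80 <- reach_discharge(ratings$q80, reaches$contrib_area_km2)
    reaches$power_q2_w <- stream_power(q2, reaches$slope)
    reaches$power_q80_w <- stream_power(q80, reaches$slope)
    reaches
  })

  reaches <- stage("forage_extraction", {
    reaches$streamside_bfi <- extract_reach_forage(reaches, bfi, 10,
                                                   width_m = reaches$width_m)
    reaches$riparian_bfi <- extract_reach_forage(reaches, bfi, 40,
                                                 width_m = reaches$width_m)
    reaches$bfi_category <- classify_bfi_category(reaches$riparian_bfi)
    reaches
  })

  reaches <- stage("fis", {
    reaches$veg_capacity_dpkm <- vegetation_capacity(reaches$streamside_bfi,
                                                     reaches$riparian_bfi)
    cap <- combined_capacity(reaches$veg_capacity_dpkm, reaches$slope,
                             reaches$power_q80_w, reaches$power_q2_w)
    reaches$capacity_dpkm <- apply_constraints(cap, reaches$width_m,
                                               reaches$contrib_area_km2,
                                               reaches$strahler_order)
    reaches$category <- categorize_capacity(reaches$capacity_dpkm)
    reaches$max_dams <- max_dams(reaches$capacity_dpkm, reaches$length_m)
    reaches
  })

  validation <- prediction <- summary_tbl <- NULL
  if (simulate) {
    reaches <- stage("observations", {
      obs <- simulate_observations(scenario, reaches)
      snapped <- snap_observations(obs, reaches)
      flag_activity(reaches, snapped)
    })
    validation <- stage("validation", {
      bfi_counts <- category_counts(reaches, reaches$bfi_category,
                                    reaches$is_active)
      act <- reaches[reaches$is_active, , drop = FALSE]
      bdc_counts <- category_counts(act, act$category, act$observed_dams > 0)
      bfi_post <- fit_category_posteriors(bfi_counts)
      bdc_post <- fit_category_posteriors(bdc_counts)
      bf_or_null <- function(post, seed)
        if (nrow(post) >= 2L) bayes_factor_matrix(post, seed = seed) else NULL
      list(bfi = list(counts = bfi_counts, posteriors = bfi_post,
                      bayes_factors = bf_or_null(bfi_post, scenario$seed + 7L)),
           bdc = list(counts = bdc_counts, posteriors = bdc_post,
                      bayes_factors = bf_or_null(bdc_post, scenario$seed + 8L)))
    })
    prediction <- stage("prediction", {
      act <- reaches[reaches$is_active, , drop = FALSE]
      if (sum(reaches$is_active) >= 50 && stats::var(act$max_dams) > 0) {
        fit <- fit_zinb(reaches[, c("observed_dams", "max_dams", "is_active")])
        pred <- predict_catchment_dams(fit, reaches,
                                       bootstrap_reps = bootstrap_reps,
                                       seed = scenario$seed + 9L)
        list(fit = fit, catchment = pred)
      } else NULL
    })
    summary_tbl <- stage("reporting", {
      pr <- if (!is.null(prediction))
        predict(prediction$fit, reaches)$expected else NULL
      aggregate_by_category(reaches, predictions = pr, aoi = "synthetic")
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("damcap")),
    r_version = as.character(getRversion()),
    seed = scenario$seed,
    scenario = scenario[setdiff(names(scenario), "occupancy_model")],
    config_md5 = {
      tf <- tempfile(fileext = ".json")
      jsonlite::write_json(scenario, tf, auto_unbox = TRUE, force = TRUE, digits = NA)
      unname(tools::md5sum(tf))
    },
    timings_s = as.list(timings))

  result <- list(reaches = reaches, bfi = bfi, ratings = ratings,
                 validation = validation, prediction = prediction,
                 summary = summary_tbl, manifest = manifest,
                 catchment = catchment)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_geojson(reaches, file.path(output_dir, "reaches.geojson"))
    write_asc(bfi, file.path(output_dir, "bfi.asc"))
    if (!is.null(summary_tbl))
      utils::write.csv(summary_tbl, file.path(output_dir, "summary.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Success/trial counts per category
#' @param data data.frame of units (reaches).
#' @param category category of each unit.
#' @param success logical success indicator per unit.
#' @return data.frame category, k, n (categories with n = 0 dropped).
#' @export
category_counts <- function(data, category, success) {
  f <- factor(category)
  n <- as.integer(table(f))
  k <- as.integer(tapply(as.logical(success), f, sum, default = 0))
  out <- data.frame(category = levels(f), k = k, n = n, stringsAsFactors = FALSE)
  out[out$n > 0, , drop = FALSE]
}
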