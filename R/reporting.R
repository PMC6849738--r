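#' Expert-validation agreement statistics
#'
#' Counts and percentages of expert agreement with mapped change clusters.
#' Percentages are over the evaluated clusters (agree + disagree), rounded
#' to the integer as printed (e.g. 48 of 51 -> 94%).
#'
#' @param verdicts Character vector over `{"agree", "disagree",
#'   "insufficient"}`, one per cluster; or a named count vector.
#' @return Named list: `n_agree`, `n_disagree`, `n_insufficient`,
#'   `n_evaluated`, `pct_agree`, `pct_disagree`.
#' @export
agreement_stats <- function(verdicts) {
  if (length(verdicts) == 0) stop("no cluster evaluations supplied")
  if (is.numeric(verdicts)) {
    cnt <- c(agree = 0, disagree = 0, insufficient = 0)
    cnt[names(verdicts)] <- verdicts
  } else {
    ok <- verdicts %in% c("agree", "disagree", "insufficient")
    if (!all(ok)) stop("unknown verdict: ", verdicts[!ok][1])
    cnt <- c(agree = sum(verdicts == "agree"),
             disagree = sum(verdicts == "disagree"),
             insufficient = sum(verdicts == "insufficient"))
  }
  n_eval <- cnt[["agree"]] + cnt[["disagree"]]
  if (n_eval == 0) stop("no evaluated clusters (all insufficient)")
  list(n_agree = cnt[["agree"]], n_disagree = cnt[["disagree"]],
       n_insufficient = cnt[["insufficient"]], n_evaluated = n_eval,
       pct_agree = round(100 * cnt[["agree"]] / n_eval),
       pct_disagree = round(100 * cnt[["disagree"]] / n_eval))
}

#' Publication-format elevation-zone table
#'
#' Formats the zone accounting in the layout of the printed elevation-zone
#' table: one row per zone with signed loss and gain areas (whole hectares),
#' percent of zone area (one decimal, when available), net change
#' (loss + gain) and a totals row summing the seven zone rows.
#'
#' @param zone_summary Either the output of [summarize_by_zone()] or a
#'   minimal data frame with columns `zone`, `loss_ha`, `gain_ha` (any
#'   `Total` row is dropped and recomputed).
#' @return Data frame `zone`, `loss_ha`, `loss_pct` (if available),
#'   `gain_ha`, `gain_pct` (if available), `net_ha` with final `Total` row.
#' @export
make_table1 <- function(zone_summary) {
  zs <- zone_summary[zone_summary$zone != "Total", , drop = FALSE]
  out <- data.frame(zone = zs$zone,
                    loss_ha = round(zs$loss_ha))
  if ("loss_pct" %in% names(zs)) out$loss_pct <- round(zs$loss_pct, 1)
  out$gain_ha <- round(zs$gain_ha)
  if ("gain_pct" %in% names(zs)) out$gain_pct <- round(zs$gain_pct, 1)
  out$net_ha <- out$loss_ha + out$gain_ha
  total <- data.frame(zone = "Total", loss_ha = sum(out$loss_ha))
  if ("loss_pct" %in% names(out)) total$loss_pct <- NA_real_
  total$gain_ha <- sum(out$gain_ha)
  if ("gain_pct" %in% names(out)) total$gain_pct <- NA_real_
  total$net_ha <- total$loss_ha + total$gain_ha
  rbind(out, total)
}

#' Publication-format model-selection table
#'
#' The best models ranked by AIC: AIC to two decimals, delta AIC to two,
#' Akaike weight to three (weights normalized over the full candidate set,
#' so the printed column sums to <= 1).
#'
#' @param ak Model table from [akaike_table()] or [select_driver_models()].
#' @param n Number of top models to print (default 4).
#' @return Data frame `model`, `aic`, `delta_aic`, `weight`.
#' @export
make_table3 <- function(ak, n = 4) {
  if (is.list(ak) && !is.data.frame(ak)) ak <- ak$table
  head <- utils::head(ak, n)
  data.frame(model = head$model,
             aic = round(head$aic, 2),
             delta_aic = round(head$delta_aic, 2),
             weight = round(head$weight, 3))
}

#' Country-by-elevation figure data
#'
#' Long-format data behind the per-country elevation-gradient bar panels:
#' per country and zone the summed significant loss and gain, plus the
#' country net (the number printed in each panel's parenthesis).
#'
#' @param country_summary Output of [summarize_by_country()].
#' @return Data frame `country`, `zone`, `loss_ha`, `gain_ha`, `net_ha`,
#'   `country_net_ha`.
#' @export
make_figure2_data <- function(country_summary) {
  bz <- country_summary$by_zone
  bz$country_net_ha <- as.numeric(country_summary$net[as.character(bz$country)])
  bz
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage on a synthetic landscape: generation, feature
#' extraction, zone-specific classification of all years, hexagon
#' tessellation and study filtering, per-hexagon trend significance
#' filtering, elevation-zone and country accounting, and driver model
#' selection. Optionally writes all tables and layers plus a run manifest.
#'
#' Zones whose training sample contains fewer than two classes are
#' classified with a fallback model trained on all samples pooled.
#'
#' @param config A [landscape_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory (created); NULL to skip writing.
#' @param n_training Training samples to digitize.
#' @param num_trees Trees per Random Forest.
#' @param eval_year Year for accuracy assessment (default the 13th study
#'   year, the printed assessment used 2013).
#' @return List of class `pipeline_result` with elements `landscape`,
#'   `models`, `maps`, `masks`, `accuracy`, `study_hexagons`, `area_ha`,
#'   `trends`, `zone_summary`, `country_summary`, `driver_records`,
#'   `driver_selection`, `manifest`.
#' @export
run_pipeline <- function(config, seed = config$seed, out_dir = NULL,
                         n_training = 1500, num_trees = 200,
                         eval_year = config$years[min(13, length(config$years))]) {
  stage_seed <- function(k) (seed * 101L + k) %% .Machine$integer.max
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ls <- stage("synthetic_landscape", generate_landscape(config, seed = stage_seed(1)))
  years <- config$years

  feats <- stage("features", build_feature_table(
    ls$composites, ls$reliability, window_mode = config$window_mode))

  samples <- stage("training_samples", sample_training_pixels(
    ls, n = n_training, ref_year = years[5], seed = stage_seed(2)))
  training <- stage("pair_samples", pair_samples(
    samples, feats[feats$year == years[5], , drop = FALSE]))

  zone_ids <- sort(unique(as.vector(ls$biome)))
  models <- stage("train_models", {
    pooled <- NULL
    out <- list()
    for (z in zone_ids) {
      nz <- training$zone == z
      if (sum(nz) >= 2 && nlevels(droplevels(training$label[nz])) >= 2) {
        out[[as.character(z)]] <- train_zone_model(
          training, z, num_trees = num_trees, seed = stage_seed(3))
      } else {
        if (is.null(pooled)) {
          all_train <- training
          all_train$zone <- 0L
          pooled <- train_zone_model(all_train, 0L, num_trees = num_trees,
                                     seed = stage_seed(3))
        }
        out[[as.character(z)]] <- pooled
      }
    }
    out
  })

  zones_px <- as.vector(ls$biome)
  maps <- stage("classify_annual", {
    lapply(stats::setNames(as.character(years), years), function(y) {
      fy <- feats[feats$year == as.integer(y), , drop = FALSE]
      fy <- fy[order(fy$pixel), , drop = FALSE]
      classify_annual(fy, models, zones_px[fy$pixel])
    })
  })
  masks <- lapply(maps, function(m) {
    matrix(binarize_woody(m, config$include_plantation_as_woody),
           config$height, config$width)
  })

  accuracy <- stage("assess_accuracy", {
    truth_eval <- LC_CLASSES[ls$truth$class[, as.character(eval_year)]]
    set.seed(stage_seed(4))
    idx <- sample.int(length(truth_eval), min(2000L, length(truth_eval)))
    assess_accuracy(as.character(maps[[as.character(eval_year)]])[idx],
                    truth_eval[idx],
                    include_plantation = config$include_plantation_as_woody)
  })

  study <- stage("hexgrid", {
    enriched <- attach_attributes(ls$grid, list(
      dem = ls$dem, country = ls$country, biome = ls$biome,
      pixel_size = config$pixel_size))
    filter_study_hexagons(enriched,
                          study_biomes = seq_along(config$biome_breaks))
  })

  area <- stage("woody_area", woody_area_by_hexagon_year(
    masks, study, pixel_size = config$pixel_size))

  trends <- stage("trend_analysis", classify_hexagons(area, alpha = config$alpha))

  zone_summary <- stage("summaries", summarize_by_zone(trends, study))
  country_summary <- summarize_by_country(trends, study)

  drivers <- stage("drivers", {
    slope <- dem_slope(ls$dem, config$pixel_size)
    mean_slope <- mean_slope_by_hexagon(slope, study, config$pixel_size)
    dpop <- rescale_to_hexagons(ls$truth$drivers, "d_rural_pop",
                                ls$municipality, study, config$pixel_size)
    dntl <- rescale_to_hexagons(ls$truth$drivers, "d_ntl",
                                ls$municipality, study, config$pixel_size)
    res <- trends$results
    sig <- res$direction != "none"
    i <- match(res$hex_id[sig], as.character(study$hex_id))
    rec <- data.frame(
      hex_id = res$hex_id[sig],
      outcome = as.integer(res$direction[sig] == "gain"),
      country = factor(study$country[i]),
      elev_class = factor(elevation_zone(study$median_elev_m[i]),
                          levels = elevation_zone_labels()),
      slope_deg = mean_slope[res$hex_id[sig]],
      d_ntl = dntl[res$hex_id[sig]],
      d_rural_pop = dpop[res$hex_id[sig]]
    )
    rec <- rec[stats::complete.cases(rec), , drop = FALSE]
    selection <- if (nrow(rec) >= 20 && length(unique(rec$outcome)) == 2) {
      terms <- driver_terms()
      ## drop single-level factors (tiny worlds may be single-country)
      if (nlevels(droplevels(rec$country)) < 2) terms <- setdiff(terms, "country")
      if (nlevels(droplevels(rec$elev_class)) < 2) terms <- setdiff(terms, "elev_class")
      rec$country <- droplevels(rec$country)
      rec$elev_class <- droplevels(rec$elev_class)
      select_driver_models(rec, terms)
    } else NULL
    list(records = rec, selection = selection)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("woodytrends")),
    r_version = R.version.string,
    master_seed = seed,
    stage_seeds = sapply(1:4, stage_seed),
    config = config[c("width", "height", "pixel_size", "hex_width_m",
                      "dropout_prob", "alpha", "window_mode")],
    n_study_hexagons = nrow(study),
    trend_counts = trends$counts
  )

  result <- structure(list(
    landscape = ls, models = models, maps = maps, masks = masks,
    accuracy = accuracy, study_hexagons = study, area_ha = area,
    trends = trends, zone_summary = zone_summary,
    country_summary = country_summary,
    driver_records = drivers$records, driver_selection = drivers$selection,
    manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}
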