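#' Linear trend of one hexagon's woody-area series
#'
#' Ordinary least squares of annual woody area (ha) on calendar year, with
#' the two-sided t test on the slope (df = n - 2). A hexagon is a gain if
#' p < alpha and the slope is positive, a loss if p < alpha and the slope is
#' negative, otherwise no trend. The net change is the observed endpoint
#' difference (last year minus first year), reported only for significant
#' hexagons; the fitted-endpoint difference is available as an option.
#'
#' @param series Numeric vector of annual areas (ha), no missing values.
#' @param years Calendar years (default 2001:2014; length must match).
#' @param alpha Significance level (default 0.05).
#' @param net Either `"observed"` (area\[last\] - area\[first\]) or
#'   `"fitted"` (slope * (last - first year)).
#' @return List of class `trend_result`: `slope` (ha/yr), `p_value`,
#'   `direction` (`"gain"`, `"loss"`, `"none"`), `net_change_ha` (NA when
#'   direction is `"none"`).
#' @export
fit_trend <- function(series, years = 2001:2014, alpha = 0.05,
                      net = c("observed", "fitted")) {
  net <- match.arg(net)
  if (length(series) != length(years)) {
    stop("series has ", length(series), " values; expected ", length(years))
  }
  if (anyNA(series)) stop("series contains missing values")
  if (stats::var(series) == 0) {
    res <- list(slope = 0, p_value = NA_real_, direction = "none",
                net_change_ha = NA_real_)
    class(res) <- "trend_result"
    return(res)
  }
  fit <- stats::lm(series ~ years)
  sm <- summary(fit)$coefficients
  slope <- sm["years", "Estimate"]
  p <- sm["years", "Pr(>|t|)"]
  direction <- if (!is.na(p) && p < alpha) {
    if (slope > 0) "gain" else "loss"
  } else "none"
  nc <- if (direction == "none") NA_real_ else if (net == "observed") {
    series[length(series)] - series[1]
  } else {
    slope * (years[length(years)] - years[1])
  }
  res <- list(slope = slope, p_value = p, direction = direction,
              net_change_ha = nc)
  class(res) <- "trend_result"
  res
}

#' Trend-filter all hexagons and count gains and losses
#'
#' Applies [fit_trend()] to every hexagon series and partitions the set into
#' gain, loss and no-trend hexagons. Percentage shares of the significant
#' set are reported to one decimal. No multiple-testing correction is
#' applied by default (each hexagon is tested at alpha); Benjamini-Hochberg
#' is available for sensitivity analysis.
#'
#' @param area_ha Matrix of areas, hexagons x years (colnames = years,
#'   rownames = hexagon ids).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param net Passed to [fit_trend()].
#' @return List of class `hexagon_trends`: `results` (data frame `hex_id`,
#'   `slope`, `p_value`, `direction`, `net_change_ha`), `counts` (named
#'   gain/loss/none), `shares` (percent of the significant set, see
#'   [direction_shares()]).
#' @export
classify_hexagons <- function(area_ha, alpha = 0.05, adjust = c("none", "BH"),
                              net = c("observed", "fitted")) {
  adjust <- match.arg(adjust)
  net <- match.arg(net)
  years <- as.numeric(colnames(area_ha))
  if (anyNA(years)) stop("area matrix must have year column names")
  fits <- apply(area_ha, 1, fit_trend, years = years, alpha = 1, net = "observed")
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  p <- vapply(fits, `[[`, numeric(1), "p_value")
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p) & p < alpha
  direction <- ifelse(sig & slope > 0, "gain",
                      ifelse(sig & slope < 0, "loss", "none"))
  endpoint <- if (net == "observed") {
    area_ha[, ncol(area_ha)] - area_ha[, 1]
  } else {
    slope * (years[length(years)] - years[1])
  }
  results <- data.frame(
    hex_id = rownames(area_ha), slope = slope, p_value = p,
    direction = direction,
    net_change_ha = ifelse(direction == "none", NA_real_, endpoint),
    row.names = NULL
  )
  counts <- c(gain = sum(direction == "gain"),
              loss = sum(direction == "loss"),
              none = sum(direction == "none"))
  structure(list(results = results, counts = counts,
                 shares = direction_shares(counts["loss"], counts["gain"])),
            class = "hexagon_trends")
}

#' Percentage shares of the significant set
#'
#' Of the hexagons with a significant trend, the percent that lost and
#' gained woody vegetation, to one decimal (e.g. counts 479 and 829 of
#' 1,308 significant give 36.6% loss / 63.4% gain). Undefined (NA) when the
#' significant set is empty.
#'
#' @param n_loss,n_gain Counts of significant loss and gain hexagons.
#' @return Named numeric vector `loss`, `gain` (percent), plus
#'   `n_significant`.
#' @export
direction_shares <- function(n_loss, n_gain) {
  n <- n_loss + n_gain
  if (n == 0) {
    return(c(loss = NA_real_, gain = NA_real_, n_significant = 0))
  }
  c(loss = round(100 * n_loss / n, 1), gain = round(100 * n_gain / n, 1),
    n_significant = n)
}

#' Elevation-zone labels
#' @return The seven zone labels, lowest first.
#' @export
elevation_zone_labels <- function() {
  c("1,000–1,499", "1,500–1,999", "2,000–2,499",
    "2,500–2,999", "3,000–3,499", "3,500–3,999", ">4,000")
}

#' Elevation zone of a median elevation
#'
#' Seven 500 m half-open bins from 1,000 m upward: `[1,000, 1,500)` through
#' `[3,500, 4,000)`, and the open-ended `[4,000, Inf)` top zone.
#'
#' @param elev_m Median elevation(s) in meters; must be >= 1,000 (lower
#'   values should have been filtered out).
#' @return Character vector of zone labels.
#' @export
elevation_zone <- function(elev_m) {
  if (any(elev_m < 1000, na.rm = TRUE)) {
    stop("elevation below 1,000 m: should have been excluded by the study filter")
  }
  labs <- elevation_zone_labels()
  labs[pmin(findInterval(elev_m, seq(1000, 4000, by = 500)), 7L)]
}

#' Elevation-zone accounting of significant woody change
#'
#' For each elevation zone: summed net change over the zone's significant
#' loss hexagons (woody loss, non-positive) and over its gain hexagons
#' (woody gain, non-negative), each also as percent of the total area of ALL study hexagons in
#' the zone, and the zone net (loss + gain). A totals row sums the columns.
#'
#' @param trends A `hexagon_trends` (or its `results` data frame).
#' @param attributes Hexagon attribute data frame with `hex_id`,
#'   `median_elev_m` and `area_ha` (per-hexagon area).
#' @return Data frame `zone`, `n_loss`, `n_gain`, `loss_ha`, `loss_pct`,
#'   `gain_ha`, `gain_pct`, `net_ha`, `zone_area_ha`, with final row
#'   `"Total"`.
#' @export
summarize_by_zone <- function(trends, attributes) {
  res <- if (inherits(trends, "hexagon_trends")) trends$results else trends
  i <- match(res$hex_id, as.character(attributes$hex_id))
  if (anyNA(i)) stop("trend results contain hexagons missing from attributes")
  zone_all <- elevation_zone(attributes$median_elev_m)
  labs <- elevation_zone_labels()
  zone_area <- vapply(labs, function(z) {
    sum(attributes$area_ha[zone_all == z])
  }, numeric(1))
  zone_res <- zone_all[i]
  one <- function(z) {
    rows <- zone_res == z
    loss <- sum(res$net_change_ha[rows & res$direction == "loss"], na.rm = TRUE)
    gain <- sum(res$net_change_ha[rows & res$direction == "gain"], na.rm = TRUE)
    data.frame(
      zone = z,
      n_loss = sum(rows & res$direction == "loss"),
      n_gain = sum(rows & res$direction == "gain"),
      loss_ha = loss,
      loss_pct = if (zone_area[z] > 0) round(100 * loss / zone_area[z], 1) else NA_real_,
      gain_ha = gain,
      gain_pct = if (zone_area[z] > 0) round(100 * gain / zone_area[z], 1) else NA_real_,
      net_ha = loss + gain,
      zone_area_ha = unname(zone_area[z])
    )
  }
  tab <- do.call(rbind, lapply(labs, one))
  total <- data.frame(
    zone = "Total", n_loss = sum(tab$n_loss), n_gain = sum(tab$n_gain),
    loss_ha = sum(tab$loss_ha), loss_pct = NA_real_,
    gain_ha = sum(tab$gain_ha), gain_pct = NA_real_,
    net_ha = sum(tab$net_ha), zone_area_ha = sum(tab$zone_area_ha)
  )
  rbind(tab, total)
}

#' Country (by elevation-zone) accounting of significant woody change
#'
#' Mirrors the per-country panels of the elevation-gradient figure: per
#' country and zone, the summed loss and gain over significant hexagons, and
#' per country the net over all its significant hexagons.
#'
#' @param trends A `hexagon_trends` (or its `results` data frame).
#' @param attributes Hexagon attributes with `hex_id`, `median_elev_m`,
#'   `area_ha` and `country`.
#' @return List: `by_zone` (data frame country x zone with `loss_ha`,
#'   `gain_ha`, `net_ha`), `net` (named per-country net, ha).
#' @export
summarize_by_country <- function(trends, attributes) {
  res <- if (inherits(trends, "hexagon_trends")) trends$results else trends
  i <- match(res$hex_id, as.character(attributes$hex_id))
  if (anyNA(i)) stop("trend results contain hexagons missing from attributes")
  ctry <- attributes$country[i]
  zone <- elevation_zone(attributes$median_elev_m[i])
  rows <- lapply(sort(unique(attributes$country)), function(cn) {
    do.call(rbind, lapply(elevation_zone_labels(), function(z) {
      sel <- !is.na(ctry) & ctry == cn & zone == z
      data.frame(
        country = cn, zone = z,
        loss_ha = sum(res$net_change_ha[sel & res$direction == "loss"], na.rm = TRUE),
        gain_ha = sum(res$net_change_ha[sel & res$direction == "gain"], na.rm = TRUE)
      )
    }))
  })
  by_zone <- do.call(rbind, rows)
  by_zone$net_ha <- by_zone$loss_ha + by_zone$gain_ha
  net <- tapply(by_zone$net_ha, by_zone$country, sum)
  list(by_zone = by_zone, net = net)
}
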