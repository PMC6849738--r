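## Land-cover class set used throughout: integer codes 1..5.
LC_CLASSES <- c("cropland", "pasture", "woody", "plantation", "other")

#' Land-cover class codes
#'
#' @return Named integer vector mapping class name to raster code.
#' @export
lc_classes <- function() stats::setNames(seq_along(LC_CLASSES), LC_CLASSES)

#' Default per-class phenology parameters
#'
#' Seasonal reflectance/index model for the five land-cover classes over the
#' five composite variables (EVI, blue, red, NIR, MIR). Each variable follows
#' `level + amp * sin(2*pi*t + phase)`; cropland gets a second harmonic on
#' EVI to mimic double cropping cycles. Levels are plausible for 250 m
#' vegetation-index composites: woody vegetation has high, stable EVI and low
#' MIR; bare/built "other" has low EVI and high MIR.
#'
#' @return Named list (one element per class) of lists with numeric vectors
#'   `level`, `amp`, `noise_sd` (length 5, named by variable), scalar `phase`
#'   and `harmonic2` (EVI second-harmonic amplitude).
#' @export
default_phenology <- function() {
  vars <- composite_variables()
  mk <- function(level, amp, noise, phase, h2 = 0) {
    list(level = stats::setNames(level, vars),
         amp = stats::setNames(amp, vars),
         noise_sd = stats::setNames(noise, vars),
         phase = phase, harmonic2 = h2)
  }
  list(
    cropland = mk(c(0.38, 0.06, 0.10, 0.30, 0.22),
                  c(0.18, 0.01, 0.03, 0.06, 0.04), rep(0.03, 5), 0.3, 0.08),
    pasture = mk(c(0.42, 0.05, 0.09, 0.28, 0.20),
                 c(0.12, 0.01, 0.02, 0.04, 0.03), rep(0.03, 5), 0.0),
    woody = mk(c(0.55, 0.04, 0.05, 0.35, 0.12),
               c(0.06, 0.005, 0.01, 0.03, 0.02), rep(0.025, 5), 0.0),
    plantation = mk(c(0.50, 0.04, 0.06, 0.40, 0.16),
                    c(0.04, 0.005, 0.01, 0.03, 0.02), rep(0.025, 5), 0.5),
    other = mk(c(0.12, 0.10, 0.18, 0.22, 0.30),
               c(0.02, 0.01, 0.01, 0.02, 0.02), rep(0.02, 5), 0.0)
  )
}

#' Composite variable names
#' @return Character vector of the five per-composite variables.
#' @export
composite_variables <- function() c("evi", "blue", "red", "nir", "mir")

#' Start day-of-year of each 16-day composite
#' @param n_composites Number of composites per year (default 23; the 23rd is
#'   short, matching the product convention).
#' @return Integer vector of start days.
#' @export
composite_doy <- function(n_composites = 23) 1L + 16L * (seq_len(n_composites) - 1L)

#' Configuration for the synthetic landscape generator
#'
#' Defines the synthetic study region: a planar equal-area world (meters) of
#' `width x height` 250 m pixels observed by 23 composites per year over
#' 2001--2014, with an elevation ramp plus smooth relief, elevation-banded
#' biomes, discrete-Voronoi countries and municipalities, class-specific
#' phenology, reliability dropouts, and scripted land-cover transitions that
#' create hexagon-level linear trends.
#'
#' @param width,height Grid size in pixels.
#' @param pixel_size Pixel edge (m), nominal 250.
#' @param years Consecutive study years.
#' @param n_composites Composites per year (>= 2).
#' @param phenology Per-class phenology, see [default_phenology()].
#' @param level_jitter_sd Per-pixel persistent offset SD added to the EVI
#'   level (bands get half), emulating sub-pixel heterogeneity.
#' @param dropout_prob Probability an observation is flagged unreliable
#'   (reliability code 3); in `[0, 1)`.
#' @param transitions Data frame of scripted conversions with columns
#'   `col_min,col_max,row_min,row_max` (pixel window), `from,to` (class
#'   names), `start_year`, `fraction` (of the window's initial `from` pixels
#'   converted per year, in `[0,1]`), or NULL for a null landscape. The
#'   default scripts emulate the study's three headline dynamics: lowland
#'   woody loss to pasture, mid-elevation pasture abandonment to woody, and
#'   highland shrub encroachment.
#' @param elev_base,elev_gradient Elevation (m) at the south edge and ramp
#'   to the north edge.
#' @param elev_noise_sd,elev_smooth_px Smooth relief field: SD (m) and
#'   smoothing radius (pixels).
#' @param n_countries,n_municipalities Number of Voronoi seed points.
#' @param biome_breaks Elevation breaks (m) separating biome bands; band 0
#'   (below the first break) is not a study biome.
#' @param hex_width_m Hexagon flat-to-flat width (m); the study geometry is
#'   11547 m but small worlds use smaller cells.
#' @param misclass_rate Transient per-pixel per-year misclassification
#'   probability used by [simulate_hexagon_series()].
#' @param pop_null_sd,pop_per_ha,ntl_null_sd,ntl_per_ha Driver-surface
#'   parameters: null SD of the municipality change variables and effect per
#'   hectare of scripted abandonment.
#' @param driver_coefs Generating logit coefficients for
#'   [simulate_driver_records()].
#' @param window_mode Feature window layout, see [build_feature_table()].
#' @param include_plantation_as_woody Whether plantation counts as woody when
#'   binarizing maps (default FALSE).
#' @param alpha Trend significance level.
#' @param seed Default random seed.
#' @return A validated config list of class `landscape_config`.
#' @export
landscape_config <- function(width = 100, height = 100, pixel_size = 250,
                             years = 2001:2014, n_composites = 23,
                             phenology = default_phenology(),
                             level_jitter_sd = 0.02,
                             dropout_prob = 0.05,
                             transitions = NULL,
                             elev_base = 800, elev_gradient = 3400,
                             elev_noise_sd = 150, elev_smooth_px = 5,
                             n_countries = 3, n_municipalities = 12,
                             biome_breaks = c(1000, 2000, 3000, 3800),
                             hex_width_m = 11547,
                             misclass_rate = 0.02,
                             pop_null_sd = 50, pop_per_ha = 2,
                             ntl_null_sd = 0.5, ntl_per_ha = 0.005,
                             driver_coefs = default_driver_coefs(),
                             window_mode = c("six", "seventeen"),
                             include_plantation_as_woody = FALSE,
                             alpha = 0.05,
                             seed = 1L) {
  window_mode <- match.arg(window_mode)
  if (is.null(transitions)) transitions <- default_transitions(width, height, years)
  stopifnot(width >= 4, height >= 4, pixel_size > 0)
  if (n_composites < 2) stop("need at least 2 composites per year")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)")
  if (!all(diff(years) == 1)) stop("years must be consecutive")
  if (nrow(transitions) > 0) {
    if (any(transitions$fraction < 0 | transitions$fraction > 1)) {
      stop("transition fractions must be in [0, 1]")
    }
    if (!all(transitions$from %in% LC_CLASSES) ||
        !all(transitions$to %in% LC_CLASSES)) {
      stop("unknown class in transitions")
    }
  }
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size, years = years, n_composites = as.integer(n_composites),
    phenology = phenology, level_jitter_sd = level_jitter_sd,
    dropout_prob = dropout_prob, transitions = transitions,
    elev_base = elev_base, elev_gradient = elev_gradient,
    elev_noise_sd = elev_noise_sd, elev_smooth_px = elev_smooth_px,
    n_countries = as.integer(n_countries),
    n_municipalities = as.integer(n_municipalities),
    biome_breaks = biome_breaks, hex_width_m = hex_width_m,
    misclass_rate = misclass_rate,
    pop_null_sd = pop_null_sd, pop_per_ha = pop_per_ha,
    ntl_null_sd = ntl_null_sd, ntl_per_ha = ntl_per_ha,
    driver_coefs = driver_coefs, window_mode = window_mode,
    include_plantation_as_woody = include_plantation_as_woody,
    alpha = alpha, seed = as.integer(seed)
  )
  class(cfg) <- "landscape_config"
  cfg
}

#' Default scripted transitions for a landscape of given size
#'
#' Three conversion scripts spanning the elevation gradient (rows run south
#' to north up the ramp): lowland woody loss to pasture, mid-elevation
#' pasture abandonment to woody regrowth, and high-elevation shrub
#' encroachment into grassland.
#'
#' @param width,height Grid size in pixels.
#' @param years Study years.
#' @return Transition data frame (see [landscape_config()]).
#' @export
default_transitions <- function(width, height, years = 2001:2014) {
  h <- height; w <- width
  data.frame(
    col_min = c(1L, 1L, as.integer(w * 0.5)),
    col_max = c(as.integer(w * 0.6), as.integer(w * 0.7), w),
    row_min = c(1L, as.integer(h * 0.35), as.integer(h * 0.75)),
    row_max = c(as.integer(h * 0.25), as.integer(h * 0.6), h),
    from = c("woody", "pasture", "pasture"),
    to = c("pasture", "woody", "woody"),
    start_year = rep(years[1], 3),
    fraction = c(0.05, 0.05, 0.04)
  )
}

## Smooth Gaussian-ish random field: white noise blurred by repeated
## moving-average passes, rescaled to unit SD.
smooth_field <- function(nr, nc, smooth_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (smooth_px >= 1) {
    k <- rep(1, 2 * smooth_px + 1)
    blur1 <- function(m) {
      ## moving average along columns with edge renormalization
      p <- smooth_px
      mpad <- rbind(m[rep(1, p), , drop = FALSE], m, m[rep(nrow(m), p), , drop = FALSE])
      out <- apply(mpad, 2, function(v) stats::filter(v, k / sum(k), sides = 2))
      out[(p + 1):(p + nrow(m)), , drop = FALSE]
    }
    for (pass in 1:2) {
      z <- blur1(z)
      z <- t(blur1(t(z)))
    }
    z <- (z - mean(z)) / stats::sd(z)
  }
  z
}

## Deterministic seasonal signal for one class: matrix [length(doy) x 5].
seasonal_signal <- function(class, doy, phenology) {
  ph <- phenology[[class]]
  if (is.null(ph)) stop("unknown class: ", class)
  t <- (doy - 1) / 365
  s1 <- sin(2 * pi * t + ph$phase)
  s2 <- sin(4 * pi * t + ph$phase)
  out <- outer(s1, ph$amp) + matrix(ph$level, length(doy), 5, byrow = TRUE)
  out[, 1] <- out[, 1] + ph$harmonic2 * s2
  colnames(out) <- composite_variables()
  out
}

#' Generate one pixel-year composite series
#'
#' Emulates a 16-day composite record for a single pixel of a given class:
#' the class seasonal signal plus independent Gaussian noise per variable,
#' EVI clipped to `[-0.2, 1]` and reflectances to `[0, 1]`, with reliability
#' codes drawn independently (0 = good, 3 = unreliable).
#'
#' @param class Land-cover class name.
#' @param year_index 1-based year index (enters the noise stream only).
#' @param phenology See [default_phenology()].
#' @param n_composites Composites per year.
#' @param dropout_prob Probability of reliability code 3.
#' @param seed Random seed (set when non-NULL).
#' @return List with `values` (n x 5 matrix), `reliability` (integer vector),
#'   `doy` (start day of each composite).
#' @export
generate_composite_series <- function(class, year_index = 1,
                                      phenology = default_phenology(),
                                      n_composites = 23,
                                      dropout_prob = 0.05, seed = NULL) {
  if (!class %in% names(phenology)) stop("unknown class: ", class)
  if (!is.null(seed)) set.seed(seed + 1000L * year_index)
  doy <- composite_doy(n_composites)
  mu <- seasonal_signal(class, doy, phenology)
  ph <- phenology[[class]]
  noise <- matrix(stats::rnorm(length(doy) * 5), length(doy), 5)
  vals <- mu + noise %*% diag(ph$noise_sd)
  colnames(vals) <- composite_variables()
  vals[, 1] <- pmin(pmax(vals[, 1], -0.2), 1)
  vals[, -1] <- pmin(pmax(vals[, -1], 0), 1)
  rel <- ifelse(stats::runif(length(doy)) < dropout_prob, 3L, 0L)
  list(values = vals, reliability = rel, doy = doy)
}

#' Generate the complete synthetic study region
#'
#' Produces every input of the downstream analysis with full truth labels:
#' DEM, biome/country/municipality rasters, per-year composite and
#' reliability stacks, the scripted per-pixel class truth, the hexagon grid
#' with true per-hexagon woody series, and municipality driver tables.
#' Deterministic for a fixed config and seed.
#'
#' @param config A [landscape_config()].
#' @param seed Random seed; defaults to `config$seed`.
#' @return List of class `synthetic_landscape` with elements `config`, `dem`,
#'   `biome`, `country`, `municipality` (matrices `[row, col]`, row 1 south),
#'   `composites` (list by year of `[n_pixels, n_composites, 5]` arrays),
#'   `reliability` (list by year of integer matrices), `grid` (hexagon
#'   layer), `hex_assign` (pixel -> hex id), and `truth` (per-pixel-per-year
#'   class matrix, per-hexagon true woody area series and direction,
#'   municipality driver table). Pixels are indexed column-major over
#'   `(row, col)`.
#' @export
generate_landscape <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(seed)
  nr <- config$height; nc <- config$width
  npix <- nr * nc
  px <- config$pixel_size
  extent <- c(0, nc * px, 0, nr * px)
  R <- hex_circumradius(config$hex_width_m)
  if (!(extent[2] - extent[1] > 2 * R) || !(extent[4] - extent[3] > config$hex_width_m)) {
    stop("grid too small to host one full hexagon of width ", config$hex_width_m, " m")
  }

  ## --- terrain -------------------------------------------------------------
  rowy <- (seq_len(nr) - 0.5) / nr
  dem <- matrix(config$elev_base + config$elev_gradient * rowy, nr, nc) +
    config$elev_noise_sd * smooth_field(nr, nc, config$elev_smooth_px)
  biome <- matrix(findInterval(dem, config$biome_breaks), nr, nc)

  ## --- administrative layers (discrete Voronoi) ----------------------------
  cc <- pixel_centers(nr, nc, px)
  voronoi_raster <- function(n_seeds) {
    sx <- stats::runif(n_seeds, extent[1], extent[2])
    sy <- stats::runif(n_seeds, extent[3], extent[4])
    d2 <- outer(cc$x, sx, `-`)^2 + outer(cc$y, sy, `-`)^2
    matrix(max.col(-d2, ties.method = "first"), nr, nc)
  }
  country <- voronoi_raster(config$n_countries)
  municipality <- voronoi_raster(config$n_municipalities)

  ## --- initial class map: elevation preference + patchy noise --------------
  opts <- c(cropland = 1600, pasture = 2500, woody = 2200,
            plantation = 2000, other = 4300)
  scales <- c(cropland = 900, pasture = 1500, woody = 1300,
              plantation = 800, other = 500)
  bases <- c(cropland = 0, pasture = 0.1, woody = 0.1,
             plantation = -0.6, other = 0)
  score <- sapply(LC_CLASSES, function(cl) {
    as.vector(bases[cl] - ((dem - opts[cl]) / scales[cl])^2 +
                0.8 * smooth_field(nr, nc, config$elev_smooth_px))
  })
  class0 <- max.col(score, ties.method = "first")

  ## --- scripted transitions ------------------------------------------------
  n_years <- length(config$years)
  truth_class <- matrix(rep(class0, n_years), npix, n_years)
  colnames(truth_class) <- config$years
  pix_row <- rep(seq_len(nr), times = nc)
  pix_col <- rep(seq_len(nc), each = nr)
  tr <- config$transitions
  code <- lc_classes()
  if (!is.null(tr) && nrow(tr) > 0) {
    for (s in seq_len(nrow(tr))) {
      in_region <- pix_col >= tr$col_min[s] & pix_col <= tr$col_max[s] &
        pix_row >= tr$row_min[s] & pix_row <= tr$row_max[s]
      eligible <- which(in_region & class0 == code[tr$from[s]])
      n0 <- length(eligible)
      if (n0 == 0) next
      ord <- sample(eligible) # fixed conversion order for the whole script
      for (t in seq_len(n_years)) {
        elapsed <- config$years[t] - tr$start_year[s] + 1
        if (elapsed <= 0) next
        k <- min(n0, floor(tr$fraction[s] * n0 * elapsed))
        if (k > 0) truth_class[ord[seq_len(k)], t] <- code[tr$to[s]]
      }
    }
  }

  ## --- composite stacks ----------------------------------------------------
  doy <- composite_doy(config$n_composites)
  nco <- length(doy)
  vars <- composite_variables()
  signals <- lapply(LC_CLASSES, function(cl) seasonal_signal(cl, doy, config$phenology))
  names(signals) <- LC_CLASSES
  noise_sd <- t(sapply(LC_CLASSES, function(cl) config$phenology[[cl]]$noise_sd))
  jit <- stats::rnorm(npix, 0, config$level_jitter_sd) # persistent per pixel
  jit_scale <- c(1, 0.5, 0.5, 0.5, 0.5)
  composites <- vector("list", n_years)
  reliability <- vector("list", n_years)
  names(composites) <- names(reliability) <- config$years
  for (t in seq_len(n_years)) {
    cl_t <- truth_class[, t]
    arr <- array(NA_real_, c(npix, nco, 5), dimnames = list(NULL, NULL, vars))
    for (v in seq_len(5)) {
      mu <- sapply(signals, function(s) s[, v])[, cl_t] # nco x npix
      val <- t(mu) + jit * jit_scale[v] +
        matrix(stats::rnorm(npix * nco), npix, nco) * noise_sd[cl_t, v]
      lo <- if (v == 1) -0.2 else 0
      arr[, , v] <- pmin(pmax(val, lo), 1)
    }
    composites[[t]] <- arr
    reliability[[t]] <- matrix(
      ifelse(stats::runif(npix * nco) < config$dropout_prob, 3L, 0L), npix, nco
    )
  }

  ## --- hexagon truth -------------------------------------------------------
  grid <- make_hexgrid(extent, config$hex_width_m)
  hex_assign <- assign_hexagons(cc$x, cc$y, grid)
  hexf <- factor(hex_assign, levels = grid$hex_id)
  pixel_area_ha <- (px / 100)^2
  woody_code <- code["woody"]
  hex_truth <- sapply(seq_len(n_years), function(t) {
    as.numeric(tapply(truth_class[, t] == woody_code, hexf, sum, default = 0L)) *
      pixel_area_ha
  })
  rownames(hex_truth) <- grid$hex_id
  colnames(hex_truth) <- config$years
  net <- hex_truth[, n_years] - hex_truth[, 1]
  hex_direction <- ifelse(net > pixel_area_ha / 2, "gain",
                          ifelse(net < -pixel_area_ha / 2, "loss", "none"))

  ls <- list(
    config = config, extent = extent, dem = dem, biome = biome,
    country = country, municipality = municipality,
    composites = composites, reliability = reliability,
    grid = grid, hex_assign = hex_assign,
    pix_row = pix_row, pix_col = pix_col,
    truth = list(class = truth_class, classes = code,
                 hex_woody_ha = hex_truth, hex_direction = hex_direction)
  )
  ls$truth$drivers <- generate_driver_surface(ls, config)
  class(ls) <- "synthetic_landscape"
  ls
}

#' Municipality-level socioeconomic driver surfaces
#'
#' Produces per-municipality change in rural population and in nighttime
#' lights (2001--2011 analogue): a Gaussian null component plus a negative
#' effect proportional to the area of scripted agricultural abandonment
#' (cropland/pasture converted to woody) inside the municipality, so that
#' abandonment municipalities lose population. The generating association
#' directions are recorded in the output.
#'
#' @param landscape A `synthetic_landscape` (or a list with `truth$class`,
#'   `municipality`, `config`).
#' @param config The landscape config.
#' @return Data frame with one row per municipality: `municipality`,
#'   `abandoned_ha`, `d_rural_pop`, `d_ntl`; attribute `"association"` gives
#'   the generating effect signs.
#' @export
generate_driver_surface <- function(landscape, config = landscape$config) {
  truth <- landscape$truth$class
  code <- lc_classes()
  abandoned <- (truth[, 1] %in% code[c("cropland", "pasture")]) &
    truth[, ncol(truth)] == code["woody"]
  muni <- as.vector(landscape$municipality)
  ids <- sort(unique(muni))
  pixel_area_ha <- (config$pixel_size / 100)^2
  ab_ha <- as.numeric(tapply(abandoned, factor(muni, levels = ids), sum,
                             default = 0L)) * pixel_area_ha
  n <- length(ids)
  out <- data.frame(
    municipality = ids,
    abandoned_ha = ab_ha,
    d_rural_pop = stats::rnorm(n, 0, config$pop_null_sd) -
      config$pop_per_ha * ab_ha,
    d_ntl = stats::rnorm(n, 0, config$ntl_null_sd) -
      config$ntl_per_ha * ab_ha
  )
  attr(out, "association") <- c(d_rural_pop = -1, d_ntl = -1)
  out
}

#' Simulate hexagon-level annual woody-area series
#'
#' Direct simulator of the per-hexagon observed woody area under a transient
#' classification-error model, used to calibrate the trend filter at scales
#' where running the pixel classifier is unnecessary: each year the observed
#' woody count is `Binomial(true_woody, 1 - e) + Binomial(n - true_woody, e)`
#' with independent errors across years, around a true count that changes
#' linearly by `trend_px_yr` pixels per year.
#'
#' @param n_hex Number of hexagons.
#' @param years Study years.
#' @param n_pixels Pixels per hexagon (default 1847, the 250 m pixel count of
#'   a 115.47 km^2 cell).
#' @param woody_frac Initial true woody fraction.
#' @param trend_px_yr True trend in pixels/year (scalar or length `n_hex`).
#' @param misclass_rate Transient per-pixel per-year misclassification
#'   probability `e`.
#' @param pixel_area_ha Pixel area (ha).
#' @param seed Random seed (set when non-NULL).
#' @return List with `area_ha` (matrix `n_hex` x years), `true_count`
#'   (matrix), `trend_px_yr` (vector).
#' @export
simulate_hexagon_series <- function(n_hex, years = 2001:2014,
                                    n_pixels = 1847, woody_frac = 0.4,
                                    trend_px_yr = 0, misclass_rate = 0.02,
                                    pixel_area_ha = 6.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_years <- length(years)
  trend <- rep_len(trend_px_yr, n_hex)
  base <- round(woody_frac * n_pixels)
  true_count <- outer(trend, seq_len(n_years) - 1) + base
  true_count <- pmin(pmax(round(true_count), 0), n_pixels)
  e <- misclass_rate
  obs <- matrix(
    stats::rbinom(n_hex * n_years, as.vector(true_count), 1 - e) +
      stats::rbinom(n_hex * n_years, n_pixels - as.vector(true_count), e),
    n_hex, n_years
  )
  area <- obs * pixel_area_ha
  colnames(area) <- colnames(true_count) <- years
  rownames(area) <- rownames(true_count) <- seq_len(n_hex)
  list(area_ha = area, true_count = true_count, trend_px_yr = trend)
}

#' Default generating coefficients for driver-record simulation
#'
#' Logit coefficients linking the probability that a significant hexagon is a
#' gain (1) rather than a loss (0) to country, elevation class and rural
#' population change: loss dominates the lowest elevation class, gain above
#' it, modest country contrasts, and a negative rural-population effect
#' (gain follows depopulation). Slope and nighttime-lights effects are zero
#' in the generator, making them pure noise terms for model selection.
#'
#' @return Named list of generating coefficients.
#' @export
default_driver_coefs <- function() {
  list(
    intercept = 0.3,
    country = c(Argentina = -0.5, Bolivia = 0.2, Colombia = 0.4,
                Ecuador = 0.1, Peru = 0.2, Venezuela = -0.4),
    elev_zone = stats::setNames(
      c(-1.2, 0.3, 0.5, 0.4, 0.3, 0.1, 0.4), elevation_zone_labels()),
    dpop = -0.004, # per person; SD(dpop) ~ 200 persons
    slope = 0,
    dntl = 0
  )
}

#' Simulate driver records for significant hexagons
#'
#' Generates `n` hexagon-level records (outcome 1 = gain, 0 = loss) from a
#' known logistic model over country, elevation class, mean slope, nighttime
#' lights change and rural population change, for parameter-recovery and
#' model-selection calibration.
#'
#' @param n Number of records.
#' @param coefs Generating coefficients, see [default_driver_coefs()].
#' @param seed Random seed (set when non-NULL).
#' @return Data frame `hex_id`, `outcome`, `country`, `elev_class`,
#'   `slope_deg`, `d_ntl`, `d_rural_pop`; generating coefficients attached as
#'   attribute `"coefs"`.
#' @export
simulate_driver_records <- function(n = 1000, coefs = default_driver_coefs(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  country <- factor(sample(names(coefs$country), n, replace = TRUE),
                    levels = names(coefs$country))
  elev <- stats::runif(n, 1000, 4600)
  zone <- factor(elevation_zone(elev), levels = elevation_zone_labels())
  slope <- stats::runif(n, 0, 35)
  dntl <- stats::rnorm(n, 0, 1)
  dpop <- stats::rnorm(n, 0, 200)
  eta <- coefs$intercept + coefs$country[as.integer(country)] +
    coefs$elev_zone[as.integer(zone)] + coefs$dpop * dpop +
    coefs$slope * slope + coefs$dntl * dntl
  outcome <- stats::rbinom(n, 1, stats::plogis(eta))
  out <- data.frame(
    hex_id = seq_len(n), outcome = outcome, country = country,
    elev_class = zone, slope_deg = slope, d_ntl = dntl, d_rural_pop = dpop
  )
  attr(out, "coefs") <- coefs
  out
}
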