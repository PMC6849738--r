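#' Terrain slope by Horn's method
#'
#' Slope in degrees from a square-cell DEM using Horn's 3x3 finite
#' difference (the standard GIS slope tool default). Edge cells use edge
#' replication.
#'
#' @param dem Elevation matrix (m), `[row, col]`.
#' @param cellsize Cell edge length (m).
#' @return Matrix of slope in degrees, same shape as `dem`.
#' @export
dem_slope <- function(dem, cellsize) {
  nr <- nrow(dem); nc <- ncol(dem)
  if (nr < 2 || nc < 2) stop("DEM must have at least 2 rows and 2 columns")
  stopifnot(cellsize > 0)
  ## pad by edge replication
  P <- rbind(dem[1, , drop = FALSE], dem, dem[nr, , drop = FALSE])
  P <- cbind(P[, 1, drop = FALSE], P, P[, nc, drop = FALSE])
  sub <- function(di, dj) P[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  ## neighborhood: rows di = -1 (below), +1 (above); cols dj = -1 (west), +1 (east)
  a <- sub(+1, -1); b <- sub(+1, 0); c_ <- sub(+1, +1)
  d <- sub(0, -1); f <- sub(0, +1)
  g <- sub(-1, -1); h <- sub(-1, 0); i_ <- sub(-1, +1)
  dzdx <- ((c_ + 2 * f + i_) - (a + 2 * d + g)) / (8 * cellsize)
  dzdy <- ((a + 2 * b + c_) - (g + 2 * h + i_)) / (8 * cellsize)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

#' Mean slope of each hexagon
#'
#' Mean of the slope raster over cells whose centers fall inside each
#' hexagon; hexagons containing no cell get NA.
#'
#' @param slope Slope matrix (degrees) from [dem_slope()].
#' @param grid Hexagon layer.
#' @param pixel_size Cell edge (m).
#' @return Named numeric vector, one value per hexagon (names = hex_id).
#' @export
mean_slope_by_hexagon <- function(slope, grid, pixel_size) {
  cc <- pixel_centers(nrow(slope), ncol(slope), pixel_size)
  hex <- assign_hexagons(cc$x, cc$y, grid)
  m <- tapply(as.vector(slope), factor(hex, levels = grid$hex_id), mean)
  stats::setNames(as.numeric(m), grid$hex_id)
}

#' Rescale municipality-level values to hexagons
#'
#' Area-weighted allocation: each hexagon receives, from every municipality
#' it overlaps, the municipality's value times the overlap fraction of the
#' municipality (overlap area / municipality area). Summed over hexagons
#' with full coverage this conserves the municipality totals. Areas are
#' pixel-count areas on the analysis grid.
#'
#' @param values Data frame with columns `municipality` and a value column.
#' @param value_col Name of the value column.
#' @param muni_raster Integer matrix of municipality ids.
#' @param grid Hexagon layer.
#' @param pixel_size Cell edge (m).
#' @return Named numeric vector per hexagon (NA where the hexagon contains
#'   no pixel).
#' @export
rescale_to_hexagons <- function(values, value_col, muni_raster, grid,
                                pixel_size) {
  cc <- pixel_centers(nrow(muni_raster), ncol(muni_raster), pixel_size)
  hex <- assign_hexagons(cc$x, cc$y, grid)
  muni <- as.vector(muni_raster)
  muni_total <- table(muni)
  val <- stats::setNames(values[[value_col]], values$municipality)
  ok <- !is.na(hex)
  overlap <- table(hex = hex[ok], muni = muni[ok])
  frac <- overlap / as.numeric(muni_total[colnames(overlap)])[col(overlap)]
  out <- as.numeric(frac %*% val[colnames(overlap)])
  names(out) <- rownames(overlap)
  full <- stats::setNames(rep(NA_real_, nrow(grid)), grid$hex_id)
  full[names(out)] <- out
  ## hexagons with pixels but zero municipality coverage cannot occur on a
  ## tessellating municipality raster; hexagons with no pixels stay NA
  full
}

#' Enumerate all main-effect model subsets
#'
#' All `2^p` subsets of the predictor terms (including the intercept-only
#' model), in deterministic order: by subset size, then by term positions.
#'
#' @param terms Character vector of predictor terms.
#' @return List of character vectors (the empty subset first).
#' @export
enumerate_models <- function(terms = driver_terms()) {
  p <- length(terms)
  subsets <- list(character(0))
  if (p > 0) {
    for (k in seq_len(p)) {
      combos <- utils::combn(terms, k, simplify = FALSE)
      subsets <- c(subsets, combos)
    }
  }
  subsets
}

#' The five driver predictors
#' @return Character vector of predictor column names.
#' @export
driver_terms <- function() {
  c("country", "elev_class", "slope_deg", "d_ntl", "d_rural_pop")
}

#' Fit one logistic model over a term subset
#'
#' Maximum-likelihood logistic regression of the gain/loss outcome on the
#' given terms (categorical terms dummy-coded against their first level).
#' `AIC = -2 logL + 2k` with `k` the number of estimated coefficients.
#' Perfectly separated fits are flagged and excluded from ranking.
#'
#' @param records Driver records: data frame with `outcome` (0 = loss,
#'   1 = gain) and the predictor columns.
#' @param terms Character vector of terms (possibly empty: intercept only).
#' @return List of class `logistic_fit`: `terms`, `fit` (glm), `aic`, `k`,
#'   `log_lik`, `separation` (logical).
#' @export
fit_logistic <- function(records, terms = character(0)) {
  if (!all(records$outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(records$outcome)) < 2) {
    stop("outcome must contain both classes")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("outcome ~", rhs))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = records))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (sep) {
    warning("possible separation in model {", rhs, "}; excluded from ranking")
  }
  structure(list(terms = terms, fit = fit, aic = stats::AIC(fit),
                 k = length(stats::coef(fit)),
                 log_lik = as.numeric(stats::logLik(fit)),
                 separation = sep),
            class = "logistic_fit")
}

#' Rank fitted models by AIC with Akaike weights
#'
#' Sorts models by AIC; `delta_aic` is each model's AIC minus the minimum,
#' and the Akaike weight is `exp(-delta/2)` normalized over ALL fitted
#' (non-separated) models, so the weights sum to 1 over the full candidate
#' set.
#'
#' @param fits List of `logistic_fit`s.
#' @return Data frame `model` (term list, `"(intercept only)"` for the empty
#'   set), `k`, `aic`, `delta_aic`, `weight`, sorted by AIC.
#' @export
akaike_table <- function(fits) {
  fits <- Filter(function(f) !f$separation, fits)
  if (!length(fits)) stop("no successful fits to rank")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  model <- vapply(fits, function(f) {
    if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept only)"
  }, character(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = model, k = k, aic = aic, delta_aic = delta,
                    weight = w)
  out <- out[order(out$aic, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive model selection over the driver predictors
#'
#' Fits every main-effect subset of the predictors and ranks by AIC.
#'
#' @param records Driver records (see [fit_logistic()]).
#' @param terms Candidate predictors (default [driver_terms()]).
#' @return List: `table` (from [akaike_table()]), `fits` (all fits, named by
#'   model string).
#' @export
select_driver_models <- function(records, terms = driver_terms()) {
  subsets <- enumerate_models(terms)
  fits <- lapply(subsets, function(s) fit_logistic(records, s))
  names(fits) <- vapply(fits, function(f) {
    if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept only)"
  }, character(1))
  list(table = akaike_table(fits), fits = fits)
}

#' Check recovery of the generating driver effects
#'
#' Given records simulated from known coefficients, fits the full model
#' enumeration and reports, for each continuous generating effect, whether
#' its sign is recovered and whether the fitted coefficient is within
#' `n_se` standard errors of truth, and whether the generating term set
#' attains `delta AIC < 2`.
#'
#' @param records Records from [simulate_driver_records()] (generating
#'   coefficients in attribute `"coefs"`, or pass `coefs`).
#' @param generating_terms Terms with nonzero generating effects.
#' @param coefs Generating coefficients (default from the records).
#' @param n_se SE multiple for the recovery band (default 3).
#' @return List: `selection` (model table), `delta_aic_generating`,
#'   `effects` (data frame per continuous term: `truth`, `estimate`, `se`,
#'   `sign_recovered`, `within_band`).
#' @export
recover_drivers <- function(records,
                            generating_terms = c("country", "elev_class", "d_rural_pop"),
                            coefs = attr(records, "coefs"), n_se = 3) {
  sel <- select_driver_models(records)
  gen_model <- paste(sort(generating_terms), collapse = " + ")
  tab_sorted <- sel$table
  tab_key <- vapply(strsplit(tab_sorted$model, " \\+ "), function(s) {
    paste(sort(trimws(s)), collapse = " + ")
  }, character(1))
  drow <- which(tab_key == gen_model)
  delta_gen <- if (length(drow)) tab_sorted$delta_aic[drow[1]] else NA_real_
  gen_fit <- fit_logistic(records, generating_terms)
  sm <- summary(gen_fit$fit)$coefficients
  cont <- intersect(generating_terms, c("slope_deg", "d_ntl", "d_rural_pop"))
  truth_of <- c(slope_deg = coefs$slope, d_ntl = coefs$dntl,
                d_rural_pop = coefs$dpop)
  effects <- do.call(rbind, lapply(cont, function(tm) {
    est <- sm[tm, "Estimate"]; se <- sm[tm, "Std. Error"]
    truth <- truth_of[[tm]]
    data.frame(term = tm, truth = truth, estimate = est, se = se,
               sign_recovered = sign(est) == sign(truth),
               within_band = abs(est - truth) <= n_se * se)
  }))
  list(selection = sel$table, delta_aic_generating = delta_gen,
       effects = effects)
}
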