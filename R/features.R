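#' Remove observations flagged unreliable
#'
#' Drops every composite whose pixel-reliability code equals 3 (unreliable:
#' cloud/snow) before any statistic is computed. Order is preserved; an empty
#' result is allowed.
#'
#' @param series A composite series: list with `values` (n x 5 matrix),
#'   `reliability` (integer vector), `doy` (integer vector).
#' @return The filtered series.
#' @export
mask_unreliable <- function(series) {
  stopifnot(nrow(series$values) == length(series$reliability))
  keep <- series$reliability != 3L
  list(values = series$values[keep, , drop = FALSE],
       reliability = series$reliability[keep],
       doy = series$doy[keep])
}

#' The five window statistics of a set of observations
#'
#' Mean, sample standard deviation (n-1 denominator), minimum, maximum and
#' range. An empty input yields all five missing (never zero); a single
#' observation yields a missing SD.
#'
#' @param x Numeric vector of already-filtered observations (NAs dropped).
#' @return Named numeric vector `mean, sd, min, max, range`.
#' @export
window_stats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    return(c(mean = NA_real_, sd = NA_real_, min = NA_real_,
             max = NA_real_, range = NA_real_))
  }
  c(mean = mean(x),
    sd = if (n > 1) stats::sd(x) else NA_real_,
    min = min(x), max = max(x), range = max(x) - min(x))
}

## Window membership of composites by start day-of-year. The default
## layout ("six") is one 12-month window, two 6-month halves and three
## 4-month thirds; "seventeen" reads "all 12 months" as 12 calendar-month
## windows and adds the halves and thirds.
feature_windows <- function(doy, window_mode = "six") {
  halves <- list(h1 = doy <= 182, h2 = doy >= 183)
  thirds <- list(t1 = doy <= 121, t2 = doy >= 122 & doy <= 243, t3 = doy >= 244)
  if (window_mode == "six") {
    c(list(annual = rep(TRUE, length(doy))), halves, thirds)
  } else {
    mstart <- cumsum(c(0, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))) + 1
    mend <- c(mstart[-1] - 1, 365)
    months <- lapply(seq_len(12), function(m) doy >= mstart[m] & doy <= mend[m])
    names(months) <- sprintf("m%02d", seq_len(12))
    c(list(annual = rep(TRUE, length(doy))), months, halves, thirds)
  }
}

#' Names of the feature columns
#'
#' @param window_mode `"six"` (150 features) or `"seventeen"` (450 features).
#' @return Character vector `<variable>_<window>_<statistic>` in the canonical
#'   order (variable outermost, statistic innermost).
#' @export
feature_names <- function(window_mode = "six") {
  wins <- names(feature_windows(composite_doy(23), window_mode))
  stats <- c("mean", "sd", "min", "max", "range")
  as.vector(t(outer(composite_variables(),
                    as.vector(t(outer(wins, stats, paste, sep = "_"))),
                    paste, sep = "_")))
}

#' Feature vector for one pixel-year
#'
#' Computes the five statistics of each composite variable over each window
#' after removing unreliable observations. Sub-annual windows that lose every
#' observation are imputed with the corresponding 12-month statistic when
#' available; if the 12-month window itself is unusable the vector is flagged
#' not usable.
#'
#' @param series Composite series (see [mask_unreliable()]).
#' @param window_mode `"six"` or `"seventeen"`.
#' @return Named numeric vector (length 150 for `"six"`) with attributes
#'   `imputed` (logical mask, TRUE where a window was back-filled from the
#'   annual window) and `usable` (scalar logical).
#' @export
build_feature_vector <- function(series, window_mode = "six") {
  s <- mask_unreliable(series)
  wins <- feature_windows(s$doy, window_mode)
  vars <- composite_variables()
  vals <- c()
  for (v in vars) {
    for (w in names(wins)) {
      st <- window_stats(s$values[wins[[w]], v])
      names(st) <- paste(v, w, names(st), sep = "_")
      vals <- c(vals, st)
    }
  }
  imputed <- rep(FALSE, length(vals))
  names(imputed) <- names(vals)
  for (v in vars) {
    ann <- vals[paste(v, "annual", c("mean", "sd", "min", "max", "range"), sep = "_")]
    for (w in setdiff(names(wins), "annual")) {
      idx <- paste(v, w, c("mean", "sd", "min", "max", "range"), sep = "_")
      miss <- is.na(vals[idx])
      vals[idx][miss] <- ann[miss]
      imputed[idx] <- miss
    }
  }
  ann_idx <- grep("_annual_", names(vals))
  attr(vals, "imputed") <- imputed
  attr(vals, "usable") <- !anyNA(vals[ann_idx]) && !anyNA(vals)
  vals
}

## Vectorized window statistics for one variable: X is [n_pixels x n_comp]
## with NA at masked observations, win a logical composite selector.
window_stats_matrix <- function(X, win) {
  Xw <- X[, win, drop = FALSE]
  n <- rowSums(!is.na(Xw))
  mu <- rowSums(Xw, na.rm = TRUE) / n
  mu[n == 0] <- NA_real_
  dev2 <- (Xw - mu)^2
  sd <- sqrt(rowSums(dev2, na.rm = TRUE) / (n - 1))
  sd[n <= 1] <- NA_real_
  mn <- do.call(pmin, c(as.data.frame(Xw), na.rm = TRUE))
  mx <- do.call(pmax, c(as.data.frame(Xw), na.rm = TRUE))
  mn[n == 0] <- NA_real_
  mx[n == 0] <- NA_real_
  cbind(mean = mu, sd = sd, min = mn, max = mx, range = mx - mn)
}

#' Per-pixel-per-year feature table
#'
#' Applies the multi-window statistics to a composite stack, one row per
#' (pixel, year). Unreliable observations (code 3) are removed first; empty
#' sub-annual windows are imputed from the annual window as in
#' [build_feature_vector()].
#'
#' @param composites List by year of `[n_pixels, n_composites, 5]` arrays
#'   (e.g. from [generate_landscape()]).
#' @param reliability List by year of `[n_pixels, n_composites]` integer
#'   matrices.
#' @param years Years to process (default: all in `composites`).
#' @param pixels Pixel indices to process (default: all). An index outside
#'   the grid is an error naming the pixel.
#' @param window_mode `"six"` or `"seventeen"`.
#' @return Data frame with columns `pixel`, `year`, the feature columns of
#'   [feature_names()], `n_imputed` and `usable`.
#' @export
build_feature_table <- function(composites, reliability,
                                years = names(composites), pixels = NULL,
                                window_mode = "six") {
  years <- as.character(years)
  if (!all(years %in% names(composites))) {
    stop("missing composite year(s): ",
         paste(setdiff(years, names(composites)), collapse = ", "))
  }
  npix_all <- dim(composites[[1]])[1]
  if (is.null(pixels)) pixels <- seq_len(npix_all)
  bad <- pixels[pixels < 1 | pixels > npix_all]
  if (length(bad)) stop("pixel outside grid: ", bad[1])
  doy <- composite_doy(dim(composites[[1]])[2])
  wins <- feature_windows(doy, window_mode)
  vars <- composite_variables()
  fnames <- feature_names(window_mode)
  out <- vector("list", length(years))
  for (yi in seq_along(years)) {
    y <- years[[yi]]
    arr <- composites[[y]]
    rel <- reliability[[y]]
    block <- matrix(NA_real_, length(pixels), length(fnames),
                    dimnames = list(NULL, fnames))
    for (v in seq_along(vars)) {
      X <- arr[pixels, , v, drop = FALSE]
      dim(X) <- dim(X)[1:2]
      X[rel[pixels, , drop = FALSE] == 3L] <- NA_real_
      for (w in names(wins)) {
        st <- window_stats_matrix(X, wins[[w]])
        block[, paste(vars[v], w, colnames(st), sep = "_")] <- st
      }
    }
    ## impute empty sub-annual windows from the annual window
    n_imputed <- integer(length(pixels))
    for (v in vars) {
      ann <- block[, paste(v, "annual",
                           c("mean", "sd", "min", "max", "range"), sep = "_"),
                   drop = FALSE]
      for (w in setdiff(names(wins), "annual")) {
        idx <- paste(v, w, c("mean", "sd", "min", "max", "range"), sep = "_")
        miss <- is.na(block[, idx, drop = FALSE])
        if (any(miss)) {
          sub <- block[, idx, drop = FALSE]
          sub[miss] <- ann[miss]
          block[, idx] <- sub
          n_imputed <- n_imputed + rowSums(miss)
        }
      }
    }
    usable <- !apply(is.na(block), 1, any)
    out[[yi]] <- data.frame(pixel = pixels, year = as.integer(y),
                            block, n_imputed = n_imputed, usable = usable,
                            check.names = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
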