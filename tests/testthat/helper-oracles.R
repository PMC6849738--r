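# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's code paths.

# Closed-form OLS of y on x via the normal equations, with the two-sided t
# test on the slope.
ols_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, se = se, t = tval, p = p)
}

# Per-cell Horn slope, straightforward loop with edge replication.
horn_oracle <- function(dem, cellsize) {
  nr <- nrow(dem); nc <- ncol(dem)
  cl <- function(i, lo, hi) min(max(i, lo), hi)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      z <- function(di, dj) dem[cl(i + di, 1, nr), cl(j + dj, 1, nc)]
      dzdx <- ((z(1, 1) + 2 * z(0, 1) + z(-1, 1)) -
                 (z(1, -1) + 2 * z(0, -1) + z(-1, -1))) / (8 * cellsize)
      dzdy <- ((z(1, -1) + 2 * z(1, 0) + z(1, 1)) -
                 (z(-1, -1) + 2 * z(-1, 0) + z(-1, 1))) / (8 * cellsize)
      out[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
    }
  }
  out
}

# A single composite series fixture with chosen values/reliability.
make_series <- function(evi, reliability = rep(0L, length(evi)),
                        doy = woodytrends::composite_doy(length(evi))) {
  vals <- cbind(evi = evi, blue = evi / 10, red = evi / 5,
                nir = evi / 2, mir = evi / 3)
  list(values = vals, reliability = as.integer(reliability), doy = doy)
}

# Small landscape config shared by several tests (fast to generate).
tiny_config <- function(...) {
  woodytrends::landscape_config(width = 40, height = 40, hex_width_m = 2500,
                                seed = 3, ...)
}

# One shared tiny pipeline run, computed lazily and cached for the session.
.pipeline_cache <- new.env()
get_tiny_pipeline <- function() {
  if (is.null(.pipeline_cache$res)) {
    .pipeline_cache$res <- woodytrends::run_pipeline(
      tiny_config(), seed = 3, n_training = 800, num_trees = 100)
  }
  .pipeline_cache$res
}
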