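test_that("Horn slope handles flat terrain, planes and matches the oracle", {
  flat <- matrix(500, 10, 12)
  expect_true(all(dem_slope(flat, 90) == 0))

  ## plane rising along x at tan(30 deg): interior cells read 30 degrees
  cell <- 90
  plane <- outer(rep(1, 10), (1:12) * cell * tan(pi / 6))
  s <- dem_slope(plane, cell)
  expect_equal(unname(s[2:9, 2:11]), matrix(30, 8, 10), tolerance = 1e-10)

  ## random smooth DEM: vectorized implementation equals per-cell loop
  set.seed(6)
  dem <- matrix(cumsum(rnorm(15 * 13, 0, 5)), 15, 13)
  expect_equal(dem_slope(dem, 90), horn_oracle(dem, 90), tolerance = 1e-12)

  ## rotating a DEM by 90 degrees preserves the multiset of slopes
  rot <- t(dem)[, rev(seq_len(nrow(dem)))]
  s1 <- dem_slope(dem, 90)[2:14, 2:12]
  s2 <- dem_slope(rot, 90)[2:12, 2:14]
  expect_equal(sort(as.vector(s1)), sort(as.vector(s2)), tolerance = 1e-10)

  expect_error(dem_slope(matrix(1, 1, 5), 90), "at least 2")
})

test_that("hexagon mean slope averages cell centers; empty cells are missing", {
  grid <- make_hexgrid(c(0, 6000, 0, 6000), width_m = 1500)
  slope <- matrix(12.5, 24, 24)
  ms <- mean_slope_by_hexagon(slope, grid, pixel_size = 250)
  has <- !is.na(ms)
  expect_true(all(abs(ms[has] - 12.5) < 1e-12))

  ## two-valued raster: mean equals count-weighted enumeration
  slope2 <- matrix(ifelse(col(slope) <= 12, 10, 20), 24, 24)
  ms2 <- mean_slope_by_hexagon(slope2, grid, pixel_size = 250)
  cx <- rep((1:24 - 0.5) * 250, each = 24)
  cy <- rep((1:24 - 0.5) * 250, times = 24)
  hex <- assign_hexagons(cx, cy, grid)
  h <- grid$hex_id[which(!is.na(ms2))[3]]
  expect_equal(unname(ms2[as.character(h)]),
               mean(as.vector(slope2)[which(hex == h)]))

  ## a grid beyond the raster has hexagons with no cells -> NA
  big <- make_hexgrid(c(0, 20000, 0, 20000), width_m = 1500)
  ms3 <- mean_slope_by_hexagon(slope, big, pixel_size = 250)
  expect_true(anyNA(ms3))
})

test_that("municipality values rescale by area weights and conserve totals", {
  grid <- make_hexgrid(c(0, 6000, 0, 6000), width_m = 1500)
  nr <- nc <- 24
  ## municipality A: west 60% of columns; B: east 40%
  muni <- matrix(ifelse(col(matrix(0, nr, nc)) <= 14, 1L, 2L), nr, nc)
  vals <- data.frame(municipality = c(1L, 2L), d_pop = c(-300, 120))
  out <- rescale_to_hexagons(vals, "d_pop", muni, grid, pixel_size = 250)

  ## conservation over full coverage
  expect_equal(sum(out, na.rm = TRUE), -300 + 120, tolerance = 1e-9)

  ## straddling hexagon: weighted sum from exact overlap enumeration
  cx <- rep((seq_len(nc) - 0.5) * 250, each = nr)
  cy <- rep((seq_len(nr) - 0.5) * 250, times = nc)
  hex <- assign_hexagons(cx, cy, grid)
  nA_tot <- sum(muni == 1); nB_tot <- sum(muni == 2)
  h <- names(which(!is.na(out)))[5]
  inh <- which(hex == as.integer(h))
  nA <- sum(as.vector(muni)[inh] == 1); nB <- sum(as.vector(muni)[inh] == 2)
  expect_equal(unname(out[h]), -300 * nA / nA_tot + 120 * nB / nB_tot,
               tolerance = 1e-9)

  ## hexagon wholly inside one municipality takes its proportional share
  all1 <- matrix(1L, nr, nc)
  v1 <- data.frame(municipality = 1L, d_pop = -300)
  out1 <- rescale_to_hexagons(v1, "d_pop", all1, grid, pixel_size = 250)
  h2 <- names(which(!is.na(out1)))[2]
  n_h <- sum(hexagons <- assign_hexagons(cx, cy, grid) == as.integer(h2), na.rm = TRUE)
  expect_equal(unname(out1[h2]), -300 * n_h / (nr * nc), tolerance = 1e-9)
})

test_that("model enumeration is exhaustive and deterministic", {
  expect_length(enumerate_models(driver_terms()), 32)
  expect_length(enumerate_models(character(0)), 1)
  two <- enumerate_models(c("A", "B"))
  expect_equal(two, list(character(0), "A", "B", c("A", "B")))
  expect_identical(enumerate_models(driver_terms()),
                   enumerate_models(driver_terms()))
})

test_that("intercept-only logistic fit matches the Bernoulli closed form", {
  rec <- data.frame(outcome = rep(c(0, 1), times = c(479, 829)))
  f <- fit_logistic(rec, character(0))
  expect_equal(unname(coef(f$fit)), log(829 / 479), tolerance = 1e-8)
  aic_closed <- -2 * (479 * log(479 / 1308) + 829 * log(829 / 1308)) + 2
  expect_equal(f$aic, aic_closed, tolerance = 1e-8)
  expect_equal(f$k, 1)
})

test_that("noise covariates stay near zero and k tracks dummy columns", {
  set.seed(14)
  n <- 2000
  rec <- data.frame(outcome = rbinom(n, 1, 0.6),
                    d_ntl = rnorm(n),
                    country = factor(sample(LETTERS[1:6], n, replace = TRUE)))
  f1 <- fit_logistic(rec, "d_ntl")
  sm <- summary(f1$fit)$coefficients
  expect_lt(abs(sm["d_ntl", "Estimate"]), 3 * sm["d_ntl", "Std. Error"])
  f2 <- fit_logistic(rec, c("d_ntl", "country"))
  expect_equal(f2$k - f1$k, 5) # 6 levels -> 5 dummy columns
  expect_error(fit_logistic(data.frame(outcome = rep(1, 10)), character(0)),
               "both classes")
})

test_that("Akaike ranking follows the closed-form weights", {
  fake <- function(aic, terms) {
    structure(list(terms = terms, aic = aic, k = 1, log_lik = NA,
                   separation = FALSE), class = "logistic_fit")
  }
  fits <- list(fake(100, "A"), fake(102, "B"), fake(110, "C"))
  tab <- akaike_table(fits)
  expect_equal(tab$delta_aic, c(0, 2, 10))
  wexp <- c(1, exp(-1), exp(-5)); wexp <- wexp / sum(wexp)
  expect_equal(tab$weight, wexp, tolerance = 1e-12)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  ## single model carries all the weight
  expect_equal(akaike_table(list(fake(50, "A")))$weight, 1)
  ## ranking invariant to a constant shift of all AICs
  tab2 <- akaike_table(list(fake(600, "A"), fake(602, "B"), fake(610, "C")))
  expect_equal(tab2$model, tab$model)
  expect_equal(tab2$weight, tab$weight, tolerance = 1e-12)
})

test_that("nested models obey the AIC bound", {
  rec <- simulate_driver_records(400, seed = 17)
  parent_terms <- c("d_rural_pop", "d_ntl", "slope_deg")
  parent <- fit_logistic(rec, parent_terms)
  for (drop in parent_terms) {
    nested <- fit_logistic(rec, setdiff(parent_terms, drop))
    extra <- parent$k - nested$k
    expect_lte(parent$aic, nested$aic + 2 * extra + 1e-9)
  }
})

test_that("generating driver effects are recovered from simulated records", {
  rec <- simulate_driver_records(1000, seed = 20)
  out <- recover_drivers(rec)
  expect_true(all(out$effects$sign_recovered))
  expect_true(all(out$effects$within_band))
  expect_equal(sum(out$selection$weight), 1, tolerance = 1e-12)
})
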