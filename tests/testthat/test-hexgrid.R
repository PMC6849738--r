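test_that("hexagon area follows the regular-hexagon closed form", {
  expect_equal(round(hexagon_area(11.547), 2), 115.47)
  expect_equal(hexagon_area(2), 2 * sqrt(3))
  w <- 3.7
  expect_equal(hexagon_area(2 * w) / hexagon_area(w), 4)
  expect_error(hexagon_area(0), "positive")
  expect_error(hexagon_area(-1), "positive")
})

test_that("the tessellation tiles without gaps or overlaps", {
  grid <- make_hexgrid(c(0, 10000, 0, 10000), width_m = 2000)
  w <- 2000; R <- w / sqrt(3)

  ## every interior cell has exactly 6 edge-sharing neighbors (centers at
  ## distance exactly one width)
  interior <- grid[grid$cx > 2500 & grid$cx < 7500 &
                     grid$cy > 2500 & grid$cy < 7500, ]
  expect_gt(nrow(interior), 0)
  for (i in seq_len(min(nrow(interior), 5))) {
    d <- sqrt((grid$cx - interior$cx[i])^2 + (grid$cy - interior$cy[i])^2)
    expect_equal(sum(abs(d - w) < 1e-6), 6)
  }

  ## brute-force audit over a lattice of probe points: every point is
  ## closed-contained by >= 1 cell, interior-contained by <= 1, and the
  ## assigned cell contains it
  px <- seq(125, 9875, by = 250)
  probes <- expand.grid(x = px, y = px)
  closed <- integer(nrow(probes))
  strict <- integer(nrow(probes))
  for (i in seq_len(nrow(grid))) {
    closed <- closed + point_in_hexagon(probes$x, probes$y,
                                        grid$cx[i], grid$cy[i], w)
    strict <- strict + point_in_hexagon(probes$x, probes$y,
                                        grid$cx[i], grid$cy[i], w,
                                        tol = -1e-9)
  }
  expect_true(all(closed >= 1))
  expect_true(all(strict <= 1))
  assigned <- assign_hexagons(probes$x, probes$y, grid)
  expect_false(anyNA(assigned))
  j <- match(assigned, grid$hex_id)
  expect_true(all(point_in_hexagon(probes$x, probes$y,
                                   grid$cx[j], grid$cy[j], w)))

  ## assignment agrees with brute-force nearest center (smallest id on ties)
  d2 <- outer(probes$x, grid$cx, `-`)^2 + outer(probes$y, grid$cy, `-`)^2
  mind <- apply(d2, 1, min)
  brute <- apply(d2 <= mind + 1e-7 * w^2, 1, function(r) min(grid$hex_id[r]))
  expect_equal(assigned, as.integer(brute))

  expect_error(make_hexgrid(c(0, 1000, 0, 1000), width_m = 2000), "larger")
})

test_that("translating the origin by one period reproduces the cell shapes", {
  ext <- c(0, 20000, 0, 20000)
  w <- 2000; R <- w / sqrt(3)
  g1 <- make_hexgrid(ext, w, origin = c(0, 0))
  g2 <- make_hexgrid(ext, w, origin = c(3 * R, w)) # one full period in x and y
  key <- function(g) sort(paste(round(g$cx, 6), round(g$cy, 6)))
  shared <- intersect(key(g1), key(g2))
  ## all interior centers coincide (sets differ only at the margins)
  expect_gt(length(shared), 0.8 * min(nrow(g1), nrow(g2)))
})

test_that("attributes attach by median, majority and any-intersection", {
  grid <- make_hexgrid(c(0, 6000, 0, 6000), width_m = 1500)
  nr <- nc <- 24; px <- 250
  rasters <- list(dem = matrix(1200, nr, nc),
                  country = matrix(1L, nr, nc),
                  biome = matrix(2L, nr, nc),
                  pixel_size = px)
  enriched <- attach_attributes(grid, rasters)
  has <- enriched$n_pixels > 0
  expect_true(all(enriched$median_elev_m[has] == 1200))
  expect_true(all(enriched$biome_2[has]))

  ## ramp DEM: median equals enumeration oracle over assigned cell centers
  dem <- matrix(seq(0, 4000, length.out = nr * nc), nr, nc)
  enr2 <- attach_attributes(grid, list(dem = dem, pixel_size = px))
  cx <- rep((seq_len(nc) - 0.5) * px, each = nr)
  cy <- rep((seq_len(nr) - 0.5) * px, times = nc)
  hex <- assign_hexagons(cx, cy, grid)
  for (h in enr2$hex_id[enr2$n_pixels > 0][c(1, 5, 9)]) {
    expect_equal(enr2$median_elev_m[enr2$hex_id == h],
                 stats::median(as.vector(dem)[which(hex == h)]))
  }

  ## majority-area country rule: split raster, check against counts
  country <- matrix(ifelse(col(matrix(0, nr, nc)) <= 10, 1L, 2L), nr, nc)
  enr3 <- attach_attributes(grid, list(dem = dem, country = country,
                                       pixel_size = px))
  for (h in enr3$hex_id[enr3$n_pixels > 0][c(2, 6)]) {
    cnt <- table(as.vector(country)[which(hex == h)])
    expect_equal(enr3$country[enr3$hex_id == h],
                 as.integer(names(cnt)[which.max(cnt)]))
  }
})

test_that("study filter applies the elevation and biome rules inclusively", {
  grid <- data.frame(hex_id = 1:4, median_elev_m = c(999, 1000, 3000, 1500),
                     biome_1 = c(TRUE, TRUE, FALSE, NA),
                     biome_2 = c(FALSE, FALSE, FALSE, FALSE))
  out <- filter_study_hexagons(grid, study_biomes = 1:2)
  expect_equal(out$hex_id, 2L)
  exc <- attr(out, "excluded")
  expect_equal(exc$reason[exc$hex_id == 1], "median elevation < 1000 m")
  expect_equal(exc$reason[exc$hex_id == 3], "no study biome intersection")
})

test_that("woody areas sum pixels into hexagons and conserve totals", {
  grid <- make_hexgrid(c(0, 6000, 0, 6000), width_m = 1500)
  nr <- nc <- 24
  all_woody <- matrix(TRUE, nr, nc)
  none <- matrix(FALSE, nr, nc)
  masks <- list("2001" = all_woody, "2002" = none)
  area <- woody_area_by_hexagon_year(masks, grid, pixel_size = 250)
  cx <- rep((seq_len(nc) - 0.5) * 250, each = nr)
  cy <- rep((seq_len(nr) - 0.5) * 250, times = nc)
  hex <- assign_hexagons(cx, cy, grid)
  npx <- table(factor(hex, levels = grid$hex_id))
  expect_equal(unname(area[, "2001"]), as.numeric(npx) * 6.25)
  expect_true(all(area[, "2002"] == 0))
  ## conservation: sum over hexagons = total woody pixels x pixel area
  expect_equal(sum(area[, "2001"]), nr * nc * 6.25)

  ## scripted conversion matches the generator truth tables
  ls <- generate_landscape(tiny_config(), seed = 5)
  woody <- lc_classes()["woody"]
  truth_masks <- lapply(seq_along(ls$config$years), function(t) {
    matrix(ls$truth$class[, t] == woody, ls$config$height, ls$config$width)
  })
  names(truth_masks) <- ls$config$years
  area2 <- woody_area_by_hexagon_year(truth_masks, ls$grid, pixel_size = 250)
  expect_equal(unname(area2), unname(ls$truth$hex_woody_ha))

  expect_error(woody_area_by_hexagon_year(list(), grid), "no annual masks")
})
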