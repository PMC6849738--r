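#' Area of a regular hexagon from its flat-to-flat width
#'
#' The analysis tessellates the study region with regular hexagons whose
#' flat-to-flat width is 11.547 km, giving cells of 115.47 km^2 (~11,547 ha).
#' For a regular hexagon the area is \eqn{(\sqrt{3}/2)\,w^2} where `w` is the
#' distance between two opposite (flat) sides.
#'
#' @param width Flat-to-flat width. The result is in the square of whatever
#'   unit `width` is given in (km -> km^2, m -> m^2).
#' @return Numeric area.
#' @examples
#' hexagon_area(11.547) # 115.47 km^2, the study cell size
#' @export
hexagon_area <- function(width) {
  if (!is.numeric(width) || any(width <= 0)) {
    stop("hexagon width must be positive")
  }
  sqrt(3) / 2 * width^2
}

## Circumradius (center-to-vertex) of a flat-topped hexagon of flat-to-flat
## width w. Flat sides face north/south so the north-south extent equals w.
hex_circumradius <- function(width) width / sqrt(3)

#' Build a regular hexagon tessellation over a rectangular extent
#'
#' Cells are flat-topped (horizontal top and bottom edges) so that the
#' north-south extent of every cell equals the flat-to-flat width. Columns of
#' centers are spaced 1.5 circumradii apart in x; alternate columns are offset
#' by half a width in y. Every point of the extent is covered by exactly one
#' cell (the tiling is the Voronoi diagram of the cell centers).
#'
#' @param extent Numeric vector `c(xmin, xmax, ymin, ymax)` in meters.
#' @param width_m Flat-to-flat cell width in meters (default 11547, the
#'   115.47 km^2 study geometry).
#' @param origin Numeric `c(x0, y0)`: a cell center is placed here. Defaults
#'   to `c(xmin, ymin)`.
#' @return A data.frame with one row per cell: `hex_id`, `hex_col`, `hex_row`,
#'   `cx`, `cy` (center, m), `area_km2`, `area_ha`, plus attributes `width_m`
#'   and `extent`.
#' @export
make_hexgrid <- function(extent, width_m = 11547, origin = extent[c(1, 3)]) {
  stopifnot(length(extent) == 4, width_m > 0)
  xmin <- extent[1]; xmax <- extent[2]; ymin <- extent[3]; ymax <- extent[4]
  R <- hex_circumradius(width_m)
  if (!(xmax - xmin > 2 * R) || !(ymax - ymin > width_m)) {
    stop("extent (", xmax - xmin, " x ", ymax - ymin,
         " m) must be strictly larger than one hexagon")
  }
  ## centers within R of the extent suffice for full coverage: the cell
  ## containing any point has its center within R of that point
  j0 <- floor((xmin - R - origin[1]) / (1.5 * R))
  j1 <- ceiling((xmax + R - origin[1]) / (1.5 * R))
  i0 <- floor((ymin - R - origin[2]) / width_m) - 1L
  i1 <- ceiling((ymax + R - origin[2]) / width_m) + 1L
  cells <- expand.grid(hex_row = i0:i1, hex_col = j0:j1)
  cells$cx <- origin[1] + cells$hex_col * 1.5 * R
  cells$cy <- origin[2] + cells$hex_row * width_m +
    (cells$hex_col %% 2) * width_m / 2
  keep <- cells$cx >= xmin - R & cells$cx <= xmax + R &
    cells$cy >= ymin - R & cells$cy <= ymax + R
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[order(cells$hex_col, cells$hex_row), , drop = FALSE]
  cells$hex_id <- seq_len(nrow(cells))
  area_m2 <- hexagon_area(width_m)
  out <- data.frame(
    hex_id = cells$hex_id, hex_col = cells$hex_col, hex_row = cells$hex_row,
    cx = cells$cx, cy = cells$cy,
    area_km2 = area_m2 / 1e6, area_ha = area_m2 / 1e4
  )
  attr(out, "width_m") <- width_m
  attr(out, "extent") <- extent
  attr(out, "origin") <- origin
  out
}

#' Vertices of one hexagon cell
#'
#' @param grid A hexagon layer from [make_hexgrid()].
#' @param hex_id Cell id.
#' @return A 6 x 2 matrix of (x, y) vertices, counter-clockwise.
#' @export
hex_vertices <- function(grid, hex_id) {
  w <- attr(grid, "width_m")
  R <- hex_circumradius(w)
  i <- match(hex_id, grid$hex_id)
  if (is.na(i)) stop("unknown hex_id ", hex_id)
  cx <- grid$cx[i]; cy <- grid$cy[i]
  cbind(
    x = cx + c(R, R / 2, -R / 2, -R, -R / 2, R / 2),
    y = cy + c(0, w / 2, w / 2, 0, -w / 2, -w / 2)
  )
}

#' Test points for containment in one hexagon
#'
#' Closed (boundary-inclusive) point-in-polygon test for a flat-topped
#' regular hexagon, by half-plane conditions.
#'
#' @param x,y Point coordinates (m).
#' @param cx,cy Hexagon center (m).
#' @param width_m Flat-to-flat width (m).
#' @param tol Boundary tolerance in meters.
#' @return Logical vector.
#' @export
point_in_hexagon <- function(x, y, cx, cy, width_m, tol = 1e-9) {
  R <- hex_circumradius(width_m)
  dx <- abs(x - cx); dy <- abs(y - cy)
  dy <= width_m / 2 + tol & width_m * dx + R * dy <= width_m * R + width_m * tol
}

#' Assign points to hexagon cells
#'
#' Each point is assigned to the cell whose center is nearest (the tiling is
#' the Voronoi diagram of its centers). Points equidistant from two or more
#' centers (cell boundaries) are resolved deterministically to the cell with
#' the smallest id.
#'
#' @param x,y Point coordinates (m).
#' @param grid Hexagon layer from [make_hexgrid()].
#' @return Integer vector of `hex_id` (NA for points outside all cells).
#' @export
assign_hexagons <- function(x, y, grid) {
  w <- attr(grid, "width_m")
  R <- hex_circumradius(w)
  n <- length(x)
  stopifnot(length(y) == n)
  ## lookup from (col, row) to id
  key <- function(col, row) paste(col, row)
  idx <- new.env(hash = TRUE)
  grid_key <- key(grid$hex_col, grid$hex_row)
  id_of <- grid$hex_id
  names(id_of) <- grid_key
  origin <- attr(grid, "origin")
  jc <- round((x - origin[1]) / (1.5 * R))
  best_d2 <- rep(Inf, n)
  cand_d2 <- vector("list", 15L)
  cand_id <- vector("list", 15L)
  k <- 0L
  for (dj in -1:1) {
    j <- jc + dj
    cxj <- origin[1] + j * 1.5 * R
    off <- (j %% 2) * w / 2
    ic <- round((y - origin[2] - off) / w)
    for (di in -2:2) {
      i <- ic + di
      cyij <- origin[2] + i * w + off
      d2 <- (x - cxj)^2 + (y - cyij)^2
      id <- unname(id_of[key(j, i)])
      d2[is.na(id)] <- Inf
      k <- k + 1L
      cand_d2[[k]] <- d2
      cand_id[[k]] <- id
    }
  }
  d2m <- do.call(cbind, cand_d2)
  idm <- do.call(cbind, cand_id)
  mind2 <- do.call(pmin, c(as.data.frame(d2m), na.rm = TRUE))
  eps <- 1e-7 * w^2
  idm[d2m > mind2 + eps] <- NA_integer_
  out <- suppressWarnings(
    do.call(pmin, c(as.data.frame(idm), na.rm = TRUE))
  )
  out[!is.finite(mind2)] <- NA_integer_
  as.integer(out)
}

#' Attach elevation, country and biome attributes to hexagons
#'
#' Median elevation is computed over DEM cells whose centers fall inside the
#' hexagon; country membership is by largest overlap area (majority cell
#' count); biome flags record any intersection. Hexagons containing no raster
#' cell get NA attributes and are excluded downstream.
#'
#' @param grid Hexagon layer from [make_hexgrid()].
#' @param rasters A list with elements
#'   `dem` (matrix), `country` (integer matrix), `biome` (integer matrix) and
#'   `pixel_size` (m). Matrices are indexed `[row, col]` with row 1 at the
#'   south edge; cell centers at `((col-0.5), (row-0.5)) * pixel_size`.
#' @return The grid with columns `median_elev_m`, `country`, `n_pixels`, and
#'   one logical `biome_<id>` column per biome id present.
#' @export
attach_attributes <- function(grid, rasters) {
  dem <- rasters$dem
  px <- rasters$pixel_size
  nr <- nrow(dem); nc <- ncol(dem)
  cc <- pixel_centers(nr, nc, px)
  hex <- assign_hexagons(cc$x, cc$y, grid)
  ok <- !is.na(hex)
  hexf <- factor(hex[ok], levels = grid$hex_id)
  grid$n_pixels <- as.integer(table(hexf))
  med <- tapply(as.vector(dem)[ok], hexf, stats::median)
  grid$median_elev_m <- as.numeric(med)[match(grid$hex_id, names(med))]
  if (!is.null(rasters$country)) {
    cv <- as.vector(rasters$country)[ok]
    maj <- tapply(cv, hexf, function(v) {
      tb <- sort(table(v), decreasing = TRUE)
      as.integer(names(tb)[1])
    })
    grid$country <- as.integer(maj)[match(grid$hex_id, names(maj))]
  }
  if (!is.null(rasters$biome)) {
    bv <- as.vector(rasters$biome)[ok]
    for (b in sort(unique(bv))) {
      flag <- tapply(bv == b, hexf, any)
      grid[[paste0("biome_", b)]] <-
        as.logical(flag)[match(grid$hex_id, names(flag))]
    }
  }
  attr(grid, "pixel_size") <- px
  grid
}

#' Select study hexagons by elevation and biome membership
#'
#' Keeps hexagons with median elevation >= `min_elev_m` (boundary inclusive)
#' that intersect at least one of the study biomes. Returns the retained
#' layer; the exclusions, with reasons, are attached as attribute
#' `"excluded"`.
#'
#' @param grid Enriched hexagon layer from [attach_attributes()].
#' @param study_biomes Integer ids of qualifying biomes.
#' @param min_elev_m Elevation threshold in meters (default 1000).
#' @return Filtered hexagon layer.
#' @export
filter_study_hexagons <- function(grid, study_biomes, min_elev_m = 1000) {
  bcols <- paste0("biome_", study_biomes)
  bcols <- bcols[bcols %in% names(grid)]
  in_biome <- if (length(bcols)) {
    Reduce(`|`, lapply(bcols, function(cl) grid[[cl]] %in% TRUE))
  } else {
    rep(FALSE, nrow(grid))
  }
  has_px <- !is.na(grid$median_elev_m)
  elev_ok <- has_px & grid$median_elev_m >= min_elev_m
  keep <- has_px & elev_ok & in_biome
  reason <- rep(NA_character_, nrow(grid))
  reason[!has_px] <- "no raster cells"
  reason[has_px & !elev_ok] <- paste0("median elevation < ", min_elev_m, " m")
  reason[has_px & elev_ok & !in_biome] <- "no study biome intersection"
  excluded <- data.frame(hex_id = grid$hex_id[!keep], reason = reason[!keep])
  out <- grid[keep, , drop = FALSE]
  attr(out, "width_m") <- attr(grid, "width_m")
  attr(out, "extent") <- attr(grid, "extent")
  attr(out, "origin") <- attr(grid, "origin")
  attr(out, "excluded") <- excluded
  out
}

#' Annual woody area per hexagon
#'
#' For each hexagon and year, sums the area of all pixels classified woody
#' (pixel membership by pixel center; nominal pixel area 6.25 ha for 250 m
#' cells).
#'
#' @param masks List (one element per year, named by year) of logical
#'   matrices, TRUE where the pixel is woody.
#' @param grid Study hexagon layer.
#' @param pixel_size Pixel edge length in meters (default 250).
#' @return A matrix of areas in hectares, hexagons in rows (rownames =
#'   hex_id), years in columns.
#' @export
woody_area_by_hexagon_year <- function(masks, grid, pixel_size = 250) {
  if (length(masks) == 0) stop("no annual masks supplied")
  if (is.null(names(masks))) stop("masks must be named by year")
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  cc <- pixel_centers(nr, nc, pixel_size)
  hex <- assign_hexagons(cc$x, cc$y, grid)
  hexf <- factor(hex, levels = grid$hex_id)
  pixel_area_ha <- (pixel_size / 100)^2
  out <- sapply(masks, function(m) {
    if (!identical(dim(m), c(nr, nc))) stop("mask dimensions differ")
    cnt <- tapply(as.vector(m), hexf, sum, default = 0L)
    as.numeric(cnt) * pixel_area_ha
  })
  out <- matrix(out, nrow = nrow(grid),
                dimnames = list(grid$hex_id, names(masks)))
  out
}

## Cell-center coordinates of an nr x nc raster with row 1 at the south edge.
pixel_centers <- function(nr, nc, pixel_size) {
  list(
    x = rep((seq_len(nc) - 0.5) * pixel_size, each = nr),
    y = rep((seq_len(nr) - 0.5) * pixel_size, times = nc)
  )
}
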