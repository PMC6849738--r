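#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by every GIS. Matrix row 1
#' is the south edge, so rows are written north-first as the format
#' requires.
#'
#' @param m Numeric matrix `[row, col]`, row 1 south.
#' @param path Output file (.asc).
#' @param cellsize Cell edge (m).
#' @param xll,yll Lower-left corner coordinates (m).
#' @param digits Significant digits to write.
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(m, path, cellsize, xll = 0, yll = 0, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", cellsize),
    "NODATA_value -9999"
  ), con)
  mm <- m
  mm[is.na(mm)] <- -9999
  for (r in rev(seq_len(nrow(mm)))) {
    writeLines(paste(signif(mm[r, ], digits), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Input .asc file.
#' @return Numeric matrix, row 1 at the south edge; attributes `cellsize`,
#'   `xll`, `yll`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, character(1), 1)
  val <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(val) <- key
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == val[["nodata_value"]]] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  attr(m, "cellsize") <- val[["cellsize"]]
  attr(m, "xll") <- val[["xllcorner"]]
  attr(m, "yll") <- val[["yllcorner"]]
  m
}

#' Write a hexagon layer as GeoJSON
#'
#' One polygon feature per hexagon with all attribute columns as
#' properties. Coordinates are the planar world coordinates (meters).
#'
#' @param grid Hexagon layer (optionally enriched).
#' @param path Output file (.geojson).
#' @return Invisibly, `path`.
#' @export
write_hexagons_geojson <- function(grid, path) {
  props <- grid[setdiff(names(grid), c("cx", "cy"))]
  features <- lapply(seq_len(nrow(grid)), function(i) {
    v <- hex_vertices(grid, grid$hex_id[i])
    ring <- rbind(v, v[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = as.list(props[i, , drop = FALSE]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) unname(ring[j, ]))))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' CSV tables (trend results, zone and country summaries, driver records
#' and model selection, accuracy), ASCII-grid rasters (DEM, final-year
#' woody mask), the study hexagon layer as GeoJSON, and a JSON run
#' manifest recording seeds and versions.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  px <- result$landscape$config$pixel_size
  f <- function(x) file.path(out_dir, x)
  utils::write.csv(result$trends$results, f("trend_results.csv"), row.names = FALSE)
  utils::write.csv(result$zone_summary, f("zone_summary.csv"), row.names = FALSE)
  utils::write.csv(make_table1(result$zone_summary), f("table1.csv"), row.names = FALSE)
  utils::write.csv(make_figure2_data(result$country_summary),
                   f("figure2_data.csv"), row.names = FALSE)
  area <- data.frame(hex_id = rownames(result$area_ha), result$area_ha,
                     check.names = FALSE)
  utils::write.csv(area, f("woody_area_by_hexagon_year.csv"), row.names = FALSE)
  utils::write.csv(result$driver_records, f("driver_records.csv"), row.names = FALSE)
  if (!is.null(result$driver_selection)) {
    utils::write.csv(make_table3(result$driver_selection, n = 32),
                     f("model_selection.csv"), row.names = FALSE)
  }
  acc <- result$accuracy
  utils::write.csv(as.data.frame(acc$table), f("confusion_matrix.csv"),
                   row.names = FALSE)
  write_ascii_grid(result$landscape$dem, f("dem.asc"), cellsize = px)
  last <- result$masks[[length(result$masks)]]
  write_ascii_grid(last + 0, f("woody_mask_final_year.asc"), cellsize = px)
  write_hexagons_geojson(result$study_hexagons, f("study_hexagons.geojson"))
  jsonlite::write_json(result$manifest, f("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list.files(out_dir, full.names = TRUE))
}
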