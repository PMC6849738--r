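#' Pair training samples with their reference-year features
#'
#' Each labeled sample is joined to the feature row of the same pixel and
#' its reference year (the acquisition year of the high-resolution imagery
#' it was digitized from): a 2005 sample pairs with the 2005 features, never
#' another year. Duplicate (pixel, year, label) rows are collapsed to one;
#' samples whose (pixel, year) is absent from the feature table, or whose
#' features are unusable, are dropped with a message.
#'
#' @param samples Data frame with columns `pixel`, `label` (one of
#'   [lc_classes()] names), `ref_year`, `zone`.
#' @param features Feature table from [build_feature_table()].
#' @return Data frame of feature columns plus `label` (factor) and `zone`;
#'   attribute `"n_dropped"` counts unmatched samples.
#' @export
pair_samples <- function(samples, features) {
  stopifnot(all(c("pixel", "label", "ref_year", "zone") %in% names(samples)))
  if (!all(samples$label %in% LC_CLASSES)) {
    stop("unknown class label: ",
         paste(setdiff(samples$label, LC_CLASSES), collapse = ", "))
  }
  samples <- unique(samples[c("pixel", "label", "ref_year", "zone")])
  key_s <- paste(samples$pixel, samples$ref_year)
  key_f <- paste(features$pixel, features$year)
  i <- match(key_s, key_f)
  usable <- !is.na(i) & features$usable[i]
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(n_dropped, " sample(s) dropped: no usable feature row")
  }
  fcols <- setdiff(names(features), c("pixel", "year", "n_imputed", "usable"))
  out <- features[i[usable], fcols, drop = FALSE]
  out$label <- factor(samples$label[usable], levels = LC_CLASSES)
  out$zone <- samples$zone[usable]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Train the Random Forest model of one mapping zone
#'
#' Fits a stock Random Forest (via \pkg{ranger}) on the training rows of one
#' mapping zone. Zones follow the biome delineations; each zone gets its own
#' model trained only on its own samples.
#'
#' @param training Paired training matrix from [pair_samples()].
#' @param zone Mapping-zone id to train.
#' @param num_trees Number of trees (default 500).
#' @param mtry Variables per split (ranger default when NULL).
#' @param seed Random seed, stored with the model.
#' @return List of class `zone_model`: `model` (ranger fit), `zone`, `seed`,
#'   `classes` (levels present in training).
#' @export
train_zone_model <- function(training, zone, num_trees = 500, mtry = NULL,
                             seed = 1L) {
  rows <- training$zone == zone
  dat <- training[rows, setdiff(names(training), "zone"), drop = FALSE]
  dat$label <- droplevels(dat$label)
  if (nlevels(dat$label) < 2) {
    stop("zone ", zone, " has fewer than 2 classes; cannot train")
  }
  fit <- ranger::ranger(
    dependent.variable.name = "label", data = dat,
    num.trees = num_trees, mtry = mtry, seed = seed, num.threads = 1,
    probability = FALSE
  )
  structure(list(model = fit, zone = zone, seed = seed,
                 classes = levels(dat$label)),
            class = "zone_model")
}

#' Classify one year into an annual land-cover map
#'
#' Applies each mapping zone's model to the pixels of that zone for one
#' year's features. Pixels with unusable features are assigned class
#' `"other"` and flagged in the `nodata` attribute.
#'
#' @param features_year Feature table rows for a single year (all pixels to
#'   map).
#' @param models Named list of `zone_model`s, names = zone ids.
#' @param zones Integer/character vector: mapping zone of each feature row.
#' @return Factor vector over [lc_classes()] names, one element per row of
#'   `features_year`, with attribute `nodata` (logical).
#' @export
classify_annual <- function(features_year, models, zones) {
  stopifnot(length(zones) == nrow(features_year))
  zone_ids <- unique(as.character(zones))
  missing <- setdiff(zone_ids, names(models))
  if (length(missing)) {
    stop("no model for mapping zone(s): ", paste(missing, collapse = ", "))
  }
  fcols <- setdiff(names(features_year),
                   c("pixel", "year", "n_imputed", "usable", "zone", "label"))
  out <- factor(rep("other", nrow(features_year)), levels = LC_CLASSES)
  nodata <- !features_year$usable
  for (z in zone_ids) {
    rows <- which(as.character(zones) == z & !nodata)
    if (!length(rows)) next
    pred <- stats::predict(models[[z]]$model,
                           data = features_year[rows, fcols, drop = FALSE],
                           num.threads = 1)$predictions
    out[rows] <- as.character(pred)
  }
  attr(out, "nodata") <- nodata
  out
}

#' Woody / non-woody mask from a land-cover map
#'
#' TRUE iff the class is `woody` (natural trees and shrubs). Plantations are
#' not woody by default — the analysis targets natural woody cover — but a
#' switch includes them for sensitivity analysis.
#'
#' @param map Factor or character vector of class names (or integer codes).
#' @param include_plantation Count plantation as woody (default FALSE).
#' @return Logical vector of the same length/shape.
#' @export
binarize_woody <- function(map, include_plantation = FALSE) {
  dims <- dim(map)
  if (is.numeric(map)) map <- LC_CLASSES[map]
  map <- as.character(map)
  woody <- map == "woody"
  if (include_plantation) woody <- woody | map == "plantation"
  dim(woody) <- dims
  woody
}

#' Confusion matrix and accuracy of a classified map
#'
#' Cross-tabulates predictions against reference labels for the full class
#' set and for the woody/non-woody collapse. Overall accuracy is
#' trace/total; user (rows = predicted) and producer (columns = reference)
#' accuracies are per class.
#'
#' @param predicted Predicted class names.
#' @param reference Reference class names (same length, > 0).
#' @param include_plantation Passed to [binarize_woody()] for the collapse.
#' @return List of class `accuracy_assessment`: `table` (5-class confusion
#'   matrix), `overall`, `users`, `producers`, `binary_table`,
#'   `binary_overall`.
#' @export
assess_accuracy <- function(predicted, reference, include_plantation = FALSE) {
  if (length(reference) == 0 || length(predicted) == 0) {
    stop("empty reference set")
  }
  stopifnot(length(predicted) == length(reference))
  p <- factor(as.character(predicted), levels = LC_CLASSES)
  r <- factor(as.character(reference), levels = LC_CLASSES)
  tab <- table(predicted = p, reference = r)
  overall <- sum(diag(tab)) / sum(tab)
  users <- diag(tab) / rowSums(tab)
  producers <- diag(tab) / colSums(tab)
  pb <- factor(ifelse(binarize_woody(p, include_plantation), "woody", "non-woody"),
               levels = c("woody", "non-woody"))
  rb <- factor(ifelse(binarize_woody(r, include_plantation), "woody", "non-woody"),
               levels = c("woody", "non-woody"))
  btab <- table(predicted = pb, reference = rb)
  structure(list(table = tab, overall = overall, users = users,
                 producers = producers, binary_table = btab,
                 binary_overall = sum(diag(btab)) / sum(btab)),
            class = "accuracy_assessment")
}

#' @export
print.accuracy_assessment <- function(x, ...) {
  cat("Overall accuracy:", sprintf("%.1f%%", 100 * x$overall), "\n")
  cat("Woody/non-woody accuracy:", sprintf("%.1f%%", 100 * x$binary_overall), "\n")
  print(x$table)
  invisible(x)
}

#' Draw labeled training samples from a synthetic landscape
#'
#' Emulates the digitization of reference pixels from high-resolution
#' imagery of a given acquisition year: samples pixels at random, labels
#' them with the true class of that year, and records the mapping zone (the
#' pixel's biome).
#'
#' @param landscape A `synthetic_landscape`.
#' @param n Number of samples.
#' @param ref_year Acquisition year of the labels.
#' @param seed Random seed (set when non-NULL).
#' @return Sample data frame for [pair_samples()].
#' @export
sample_training_pixels <- function(landscape, n = 1500,
                                   ref_year = landscape$config$years[5],
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npix <- nrow(landscape$truth$class)
  pix <- sample.int(npix, min(n, npix))
  y <- as.character(ref_year)
  data.frame(
    pixel = pix,
    label = LC_CLASSES[landscape$truth$class[pix, y]],
    ref_year = as.integer(ref_year),
    zone = as.vector(landscape$biome)[pix]
  )
}
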