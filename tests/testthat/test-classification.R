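# Small synthetic training frames used across the classification tests.
fake_features <- function(pixels, years, sep = 3) {
  ## two well-separated feature columns keyed to pixel parity
  g <- expand.grid(pixel = pixels, year = years)
  set.seed(99)
  g$f1 <- ifelse(g$pixel %% 2 == 0, sep, -sep) + rnorm(nrow(g), 0, 0.3)
  g$f2 <- rnorm(nrow(g))
  g$n_imputed <- 0L
  g$usable <- TRUE
  g
}

test_that("samples pair with their reference year only", {
  feats <- fake_features(1:10, 2004:2006)
  feats$f1[feats$year == 2005] <- 111 # marker for the 2005 rows
  samples <- data.frame(pixel = c(1, 2, 3), label = "woody",
                        ref_year = 2005, zone = 1)
  tr <- pair_samples(samples, feats)
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$f1 == 111))

  ## duplicates collapse to one; empty input gives an empty matrix
  dup <- rbind(samples, samples)
  expect_equal(nrow(pair_samples(dup, feats)), 3)
  none <- samples[0, ]
  expect_equal(nrow(pair_samples(none, feats)), 0)

  ## unmatched (pixel, year) dropped with a count
  bad <- data.frame(pixel = 999, label = "woody", ref_year = 2005, zone = 1)
  expect_message(out <- pair_samples(rbind(samples, bad), feats), "dropped")
  expect_equal(attr(out, "n_dropped"), 1)
  expect_equal(nrow(out), 3)

  expect_error(pair_samples(transform(samples, label = "jungle"), feats),
               "unknown class")
})

test_that("zone models separate separable classes and are deterministic", {
  feats <- fake_features(1:200, 2005)
  samples <- data.frame(pixel = 1:200,
                        label = ifelse(1:200 %% 2 == 0, "woody", "pasture"),
                        ref_year = 2005, zone = 1)
  tr <- pair_samples(samples, feats)
  m <- train_zone_model(tr, zone = 1, num_trees = 100, seed = 7)
  pred <- predict(m$model, data = tr[c("f1", "f2")], num.threads = 1)$predictions
  expect_equal(mean(as.character(pred) == as.character(tr$label)), 1) # resubstitution on separable data

  m2 <- train_zone_model(tr, zone = 1, num_trees = 100, seed = 7)
  pred2 <- predict(m2$model, data = tr[c("f1", "f2")], num.threads = 1)$predictions
  expect_identical(pred, pred2)

  single <- transform(tr, label = factor("woody", levels = levels(tr$label)))
  expect_error(train_zone_model(single, zone = 1), "fewer than 2 classes")
})

test_that("label-permuted training yields chance-level held-out accuracy", {
  set.seed(5)
  feats <- fake_features(1:400, 2005)
  labels <- sample(rep(c("woody", "pasture"), each = 200)) # no signal
  samples <- data.frame(pixel = 1:400, label = labels, ref_year = 2005, zone = 1)
  tr <- pair_samples(samples, feats)
  idx <- 1:200
  m <- train_zone_model(tr[idx, ], zone = 1, num_trees = 200, seed = 3)
  held <- tr[-idx, ]
  pred <- predict(m$model, data = held[c("f1", "f2")], num.threads = 1)$predictions
  acc <- mean(as.character(pred) == as.character(held$label))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / nrow(held)))
})

test_that("zone predictions do not depend on other zones' samples", {
  feats <- fake_features(1:200, 2005)
  samples <- data.frame(pixel = 1:200,
                        label = ifelse(1:200 %% 2 == 0, "woody", "pasture"),
                        ref_year = 2005,
                        zone = rep(1:2, each = 100))
  tr <- pair_samples(samples, feats)
  mA <- train_zone_model(tr, zone = 1, num_trees = 100, seed = 2)
  trB_perturbed <- tr
  flip <- trB_perturbed$zone == 2
  trB_perturbed$label[flip] <- sample(trB_perturbed$label[flip])
  mA2 <- train_zone_model(trB_perturbed, zone = 1, num_trees = 100, seed = 2)
  newdata <- fake_features(301:340, 2005)
  p1 <- predict(mA$model, data = newdata[c("f1", "f2")], num.threads = 1)$predictions
  p2 <- predict(mA2$model, data = newdata[c("f1", "f2")], num.threads = 1)$predictions
  expect_identical(p1, p2)
})

test_that("annual classification recovers a disjoint-phenology checkerboard", {
  ## checkerboard of two classes with disjoint features
  feats <- fake_features(1:400, 2013)
  truth <- ifelse(1:400 %% 2 == 0, "woody", "pasture")
  samples <- data.frame(pixel = 1:400, label = truth, ref_year = 2013, zone = 1)
  tr <- pair_samples(samples, feats)
  models <- list("1" = train_zone_model(tr, 1, num_trees = 100, seed = 1))
  map <- classify_annual(feats, models, zones = rep(1, 400))
  expect_gte(mean(as.character(map) == truth), 0.99)

  ## identical feature stacks for two years give identical maps
  map2 <- classify_annual(feats, models, zones = rep(1, 400))
  expect_identical(as.character(map), as.character(map2))

  ## unusable rows become 'other' and are flagged
  feats$usable[1:5] <- FALSE
  map3 <- classify_annual(feats, models, zones = rep(1, 400))
  expect_true(all(as.character(map3)[1:5] == "other"))
  expect_true(all(attr(map3, "nodata")[1:5]))

  expect_error(classify_annual(feats, models, zones = rep(2, 400)),
               "no model for mapping zone")
})

test_that("woody binarization treats plantation per the convention", {
  m <- c("woody", "plantation", "pasture", "woody")
  expect_equal(binarize_woody(m), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(binarize_woody(m, include_plantation = TRUE),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(sum(binarize_woody(rep("plantation", 10))), 0)
  expect_equal(sum(binarize_woody(rep("woody", 10))), 10)
  ## integer-coded maps work too
  expect_equal(binarize_woody(c(3L, 1L)), c(TRUE, FALSE))
})

test_that("accuracy assessment computes trace/total and the binary collapse", {
  ref <- rep(c("woody", "pasture"), each = 50)
  expect_equal(assess_accuracy(ref, ref)$overall, 1)

  ## 2x2 counts [[45,5],[5,45]] -> 90%
  pred <- c(rep("woody", 45), rep("pasture", 5), rep("pasture", 45), rep("woody", 5))
  a <- assess_accuracy(pred, ref)
  expect_equal(a$overall, 0.9)
  expect_equal(a$binary_overall, 0.9)

  ## collapsing cannot decrease matched pairs
  set.seed(10)
  pred5 <- sample(names(lc_classes()), 200, replace = TRUE)
  ref5 <- sample(names(lc_classes()), 200, replace = TRUE)
  a5 <- assess_accuracy(pred5, ref5)
  expect_gte(a5$binary_overall, a5$overall)

  expect_error(assess_accuracy(character(0), character(0)), "empty reference")
})
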