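# Trainable segmentation stage: determinism, augmentation, training, prediction.

test_that("unknown backends are rejected with the available list", {
  expect_error(init_model("rcnn"), "available backends.*ref")
})

test_that("initialization and training are deterministic for a fixed seed", {
  m1 <- init_model("ref", seed = 4)
  m2 <- init_model("ref", seed = 4)
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, init_model("ref", seed = 5)$weights))

  cfg <- generator_config("easy")
  train_set <- generate_annotated(cfg, 3, seed = 8)
  proto <- training_protocol("primary", epochs = 3, seed = 8)
  f1 <- train_model(m1, train_set, proto)
  f2 <- train_model(m2, train_set, proto)
  expect_identical(f1$log$mean_loss, f2$log$mean_loss)
  img <- generate_annotated(cfg, 1, seed = 99)[[1]]
  expect_identical(predict(f1$model, img, 0.5), predict(f2$model, img, 0.5))
})

test_that("warm start copies parameters and inherits lineage; class mismatch reinitializes the head", {
  cfg <- generator_config("easy")
  fit <- train_model(init_model(seed = 1), generate_annotated(cfg, 3, seed = 2),
                     training_protocol("primary", epochs = 2, seed = 2))
  warm <- init_model("ref", warm_start = fit$model, seed = 9)
  expect_identical(warm$weights, fit$model$weights)
  expect_identical(warm$lineage, fit$model$lineage)
  expect_warning(
    mixed <- init_model("ref", class_set = c("crystal", "cell"),
                        warm_start = fit$model, seed = 9),
    "re-initializing"
  )
  expect_identical(mixed$weights[, "crystal"], fit$model$weights[, "crystal"])
  expect_false(identical(mixed$weights[, "cell"], fit$model$weights[, "crystal"]))
})

test_that("flips are involutions and transform coordinates correctly", {
  img <- matrix(runif(64 * 48), 48, 64)  # non-square to catch axis mixups
  poly <- rbind(c(10, 5), c(20, 5), c(20, 12), c(10, 12))
  inst <- tibble::tibble(label = "crystal", polygon = list(poly))
  once <- cellcryst:::apply_augment_image(img, inst, list(hflip = TRUE, vflip = FALSE, crop = NULL))
  twice <- cellcryst:::apply_augment_image(once$image, once$instances,
                                           list(hflip = TRUE, vflip = FALSE, crop = NULL))
  expect_identical(twice$image, img)
  expect_equal(twice$instances$polygon[[1]], poly, ignore_attr = TRUE)
  # flipping moves a mask centroid x to width-1-x (pixel-index coordinates)
  mask <- rasterize_polygon(poly, dim(img))
  ctr <- cellcryst:::mask_centroid(mask)
  flipped_mask <- rasterize_polygon(once$instances$polygon[[1]], dim(img))
  ctr_f <- cellcryst:::mask_centroid(flipped_mask)
  # in half-open pixel coordinates: x' = width - x
  expect_equal(unname(ctr_f["x"]), ncol(img) - unname(ctr["x"]))
  expect_equal(unname(ctr_f["y"]), unname(ctr["y"]))
})

test_that("random crops keep at least half the area and never drop all instances", {
  img <- matrix(runif(64 * 64), 64, 64)
  poly <- rbind(c(30, 30), c(40, 30), c(40, 40), c(30, 40))
  inst <- tibble::tibble(label = "crystal", polygon = list(poly))
  proto <- training_protocol("primary", augmentations = c("hflip", "vflip", "random_crop"))
  for (seed in 1:25) {
    out <- augment_sample(img, inst, proto, seed = seed)
    expect_gte(nrow(out$image) * ncol(out$image), 0.5 * 64 * 64 - 64)
    expect_gte(nrow(out$instances), 1)
  }
})

test_that("training reduces the loss, validates inputs, and extends the lineage", {
  cfg <- generator_config("easy")
  train_set <- generate_annotated(cfg, 6, seed = 14)
  fit <- train_model(init_model(seed = 3), train_set, training_protocol("primary", seed = 3))
  expect_lt(tail(fit$log$mean_loss, 1), fit$log$mean_loss[1])
  expect_equal(nrow(fit$log), 40)
  expect_equal(nrow(fit$model$lineage), 1)
  expect_equal(fit$model$lineage$role, "primary")

  expect_error(training_protocol("primary", epochs = 0), "epochs")
  expect_error(training_protocol("primary", learning_rate = -1), "learning_rate")
  expect_error(train_model(init_model(seed = 1), list(), training_protocol("primary")), "empty")

  fit2 <- train_model(fit$model, train_set[1:2],
                      training_protocol("secondary", seed = 4))
  expect_equal(nrow(fit2$model$lineage), 2)
  expect_equal(fit2$model$lineage$role, c("primary", "secondary"))
  expect_equal(fit2$model$lineage$epochs, c(40L, 10L))
})

test_that("a trained model recovers high-contrast crystals and stays quiet on blank images", {
  run <- easy_learning_f(301)
  model <- run$fit$model
  img <- run$test_set[[1]]
  preds <- predict(model, img, score_threshold = 0.7)
  expect_s3_class(preds, "crystal_predictions")
  expect_gte(nrow(preds), 1)
  # scores sorted descending, all above threshold, boxes tight
  expect_true(all(diff(preds$score) <= 0))
  expect_true(all(preds$score >= 0.7))
  for (i in seq_len(nrow(preds))) {
    bb <- cellcryst:::mask_bbox(preds$mask[[i]])
    expect_equal(c(preds$xmin[i], preds$ymin[i], preds$xmax[i], preds$ymax[i]),
                 bb, ignore_attr = TRUE)
    expect_gte(sum(preds$mask[[i]]), model$min_component_px)
  }
  # threshold monotonicity
  n_preds <- vapply(c(0.2, 0.5, 0.8, 0.95),
                    function(t) nrow(predict(model, img, t)), numeric(1))
  expect_true(all(diff(n_preds) <= 0))
  # threshold 1.0 keeps only exact-1 scores (typically none)
  p1 <- predict(model, img, score_threshold = 1)
  expect_true(all(p1$score == 1))
  # blank background image -> no detections
  blank <- matrix(0.82, 128, 128)
  expect_equal(nrow(predict(model, blank, 0.7)), 0)
})

test_that("checkpoint save/load reproduces predictions bit-identically", {
  run <- easy_learning_f(301)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(run$fit$model, path)
  back <- load_model(path)
  expect_identical(back$weights, run$fit$model$weights)
  expect_identical(back$lineage$fingerprint, run$fit$model$lineage$fingerprint)
  img <- run$test_set[[2]]
  expect_identical(predict(back, img, 0.5), predict(run$fit$model, img, 0.5))
})

test_that("warm-started training starts from a lower loss than a cold start", {
  cfg <- generator_config("easy")
  new_data <- generate_annotated(cfg, 4, seed = 880)
  losses <- vapply(c(301, 302), function(seed) {
    run <- easy_learning_f(seed)
    warm <- train_model(run$fit$model, new_data,
                        training_protocol("secondary", epochs = 1, seed = 71))
    cold <- train_model(init_model(seed = 71), new_data,
                        training_protocol("secondary", epochs = 1, seed = 71))
    warm$log$mean_loss[1] - cold$log$mean_loss[1]
  }, numeric(1))
  expect_lt(mean(losses), 0)
})

test_that("the reference backend learns the easy regime to mean F >= 0.70 (2 seeds)", {
  for (seed in c(301, 302)) {
    run <- easy_learning_f(seed)
    expect_gte(run$report$averages$f_measure, 0.70)
  }
})
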