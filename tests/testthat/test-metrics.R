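# Evaluation metrics: worked examples, algebraic identities, oracle checks.

test_that("pixel confusion counts match hand enumeration on a 2x2 image", {
  pred <- matrix(FALSE, 2, 2); pred[1, 1] <- pred[1, 2] <- pred[2, 1] <- TRUE
  gt <- matrix(FALSE, 2, 2); gt[1, 2] <- gt[2, 1] <- gt[2, 2] <- TRUE
  conf <- pixel_confusion(list(pred), list(gt), c(2, 2))
  expect_equal(conf$tp, 2)
  expect_equal(conf$fp, 1)
  expect_equal(conf$fn, 1)
  same <- pixel_confusion(list(gt), list(gt), c(2, 2))
  expect_equal(same$fp + same$fn, 0)
  none <- pixel_confusion(list(), list(gt), c(2, 2))
  expect_equal(none$tp, 0); expect_equal(none$fp, 0); expect_equal(none$fn, 3)
  expect_error(pixel_confusion(list(pred), list(matrix(FALSE, 3, 3)), c(2, 2)), "shape")
})

test_that("worked example: tp=2, fp=1, fn=1 gives P=R=F=2/3 and J=1/2 exactly", {
  conf <- tibble::tibble(tp = 2, fp = 1, fn = 1)
  expect_identical(precision(conf), 2 / 3)
  expect_identical(recall(conf), 2 / 3)
  expect_identical(f_measure(conf), 2 / 3)
  expect_identical(jaccard(conf), 0.5)
})

test_that("degenerate images follow the declared conventions", {
  both_empty <- tibble::tibble(tp = 0, fp = 0, fn = 0)
  expect_equal(unlist(cellcryst:::confusion_rates(both_empty)), c(precision = 1, recall = 1, f_measure = 1, jaccard = 1))
  hallucination <- tibble::tibble(tp = 0, fp = 5, fn = 0)
  miss <- tibble::tibble(tp = 0, fp = 0, fn = 5)
  for (c in list(hallucination, miss)) {
    expect_equal(f_measure(c), 0)
    expect_equal(jaccard(c), 0)
  }
})

test_that("J = F / (2 - F) for every confusion with tp+fp+fn > 0", {
  set.seed(19)
  conf <- tibble::tibble(
    tp = sample(0:50, 1000, replace = TRUE),
    fp = sample(0:50, 1000, replace = TRUE),
    fn = sample(0:50, 1000, replace = TRUE)
  )
  conf <- conf[conf$tp + conf$fp + conf$fn > 0, ]
  f <- f_measure(conf)
  expect_equal(jaccard(conf), f / (2 - f), tolerance = 1e-12)
})

test_that("pixel metrics match the enumeration oracle on random mask pairs", {
  set.seed(77)
  for (i in 1:200) {
    pred <- matrix(runif(256) < runif(1, 0.05, 0.5), 16, 16)
    gt <- matrix(runif(256) < runif(1, 0.05, 0.5), 16, 16)
    oc <- oracle_confusion(pred, gt)
    conf <- pixel_confusion(list(pred), list(gt), c(16, 16))
    expect_identical(as.integer(conf$tp), oc$tp)
    expect_identical(as.integer(conf$fp), oc$fp)
    expect_identical(as.integer(conf$fn), oc$fn)
    # rates from integer counts are exact rationals; compare exactly
    if (oc$tp + oc$fp > 0) expect_identical(precision(conf), oc$tp / (oc$tp + oc$fp))
    if (oc$tp + oc$fn > 0) expect_identical(recall(conf), oc$tp / (oc$tp + oc$fn))
    if (oc$tp + oc$fp + oc$fn > 0) {
      expect_identical(jaccard(conf), oc$tp / (oc$tp + oc$fp + oc$fn))
    }
  }
})

test_that("object-count error follows its formula, including the cancellation case", {
  counts <- tibble::tibble(gt_count = c(4, 2), pred_count = c(3, 2))
  expect_identical(delta_object(counts), 0.5)
  expect_identical(delta_object_normalized(counts), 0.125)
  # one miss plus one spurious detection on the same image cancel out
  cancel <- tibble::tibble(gt_count = 2, pred_count = 2)
  expect_identical(delta_object(cancel), 0)
  perfect <- tibble::tibble(gt_count = c(3, 1, 5), pred_count = c(3, 1, 5))
  expect_identical(delta_object(perfect), 0)
  expect_identical(delta_object_normalized(perfect), 0)
  expect_error(delta_object(tibble::tibble(gt_count = integer(), pred_count = integer())), "at least one")
})

test_that("normalized object error is capped at 1 and handles empty images", {
  expect_identical(delta_object_normalized(tibble::tibble(gt_count = 2, pred_count = 7)), 1)
  expect_identical(delta_object_normalized(tibble::tibble(gt_count = 0, pred_count = 0)), 0)
  expect_identical(delta_object_normalized(tibble::tibble(gt_count = 0, pred_count = 3)), 1)
  # symmetry: over- and under-segmentation by k contribute equally
  set.seed(5)
  for (i in 1:20) {
    g <- sample(2:10, 1); k <- sample(1:(g - 1), 1)
    over <- tibble::tibble(gt_count = g, pred_count = g + k)
    under <- tibble::tibble(gt_count = g, pred_count = g - k)
    expect_identical(delta_object(over), delta_object(under))
    expect_identical(delta_object_normalized(over), delta_object_normalized(under))
  }
})

test_that("pixel metrics see unions; object counts see instances", {
  # one rectangle vs the same pixels split into two abutting instances
  whole_poly <- rbind(c(1, 1), c(14, 1), c(14, 6), c(1, 6))
  left_poly <- rbind(c(1, 1), c(8, 1), c(8, 6), c(1, 6))
  right_poly <- rbind(c(8, 1), c(14, 1), c(14, 6), c(8, 6))
  gt_whole <- annotated_image(
    image = matrix(0, 16, 16),
    instances = tibble::tibble(label = "crystal", polygon = list(whole_poly))
  )
  gt_split <- annotated_image(
    image = matrix(0, 16, 16),
    instances = tibble::tibble(label = c("crystal", "crystal"),
                               polygon = list(left_poly, right_poly))
  )
  pred <- list(tibble::tibble(label = "crystal", score = 1,
                              mask = list(rasterize_polygon(whole_poly, c(16, 16)))))
  rep_whole <- evaluate_dataset(pred, list(gt_whole), 0.5)
  rep_split <- evaluate_dataset(pred, list(gt_split), 0.5)
  # same pixels -> same F and J
  expect_equal(rep_split$averages$f_measure, rep_whole$averages$f_measure)
  expect_equal(rep_split$averages$jaccard, rep_whole$averages$jaccard)
  # different instance structure -> different object counts
  expect_equal(rep_whole$averages$delta_o, 0)
  expect_equal(rep_split$averages$delta_o, 1)
  expect_gt(rep_split$averages$delta_on, 0)
})

test_that("perfect predictions over synthetic images give F = J = 1 and zero count error", {
  cfg <- generator_config("desk", crystal_classes = c("G", "H"))
  gts <- generate_annotated(cfg, 5, seed = 21)
  preds <- lapply(gts, function(a) {
    masks <- instance_masks(a, labels = "^crystal")
    tibble::tibble(label = rep("crystal", length(masks)),
                   score = rep(1, length(masks)), mask = masks)
  })
  rep <- evaluate_dataset(preds, gts, score_threshold = 0.7)
  expect_identical(rep$averages$f_measure, 1)
  expect_identical(rep$averages$jaccard, 1)
  expect_identical(rep$averages$delta_o, 0)
  expect_identical(rep$averages$delta_on, 0)
  expect_equal(rep$n, 5)
})

test_that("mean J never exceeds mean F, and thresholding is monotone", {
  set.seed(31)
  shape <- c(16, 16)
  gts <- lapply(1:6, function(i) {
    m <- matrix(runif(256) < 0.2, 16, 16)
    if (!any(m)) m[3, 3] <- TRUE
    annotated_image(image = matrix(0, 16, 16),
                    instances = tibble::tibble(label = "crystal",
                                               polygon = list(mask_to_polygon(m))))
  })
  preds <- lapply(1:6, function(i) {
    k <- sample(1:4, 1)
    tibble::tibble(
      label = rep("crystal", k),
      score = runif(k),
      mask = lapply(1:k, function(j) matrix(runif(256) < 0.2, 16, 16))
    )
  })
  last_counts <- rep(Inf, 6)
  for (thr in c(0, 0.3, 0.6, 0.9)) {
    rep <- evaluate_dataset(preds, gts, score_threshold = thr)
    expect_lte(rep$averages$jaccard, rep$averages$f_measure + 1e-12)
    expect_true(all(rep$per_image$pred_count <= last_counts))
    last_counts <- rep$per_image$pred_count
  }
})

test_that("box-score contexts partition predictions by host-cell occupancy", {
  cell1 <- matrix(FALSE, 20, 20); cell1[2:10, 2:10] <- TRUE
  cell2 <- matrix(FALSE, 20, 20); cell2[12:19, 12:19] <- TRUE
  blob <- function(r, c) { m <- matrix(FALSE, 20, 20); m[r, c] <- TRUE; m }
  preds <- tibble::tibble(
    label = "crystal",
    score = c(0.8, 1.0, 0.9),
    mask = list(blob(3:4, 3:4), blob(7:8, 7:8), blob(14:15, 14:15))
  )
  out <- mean_box_score(list(preds), context = c("all", "isolated_in_cell", "coexisting_in_cell"),
                        cells = list(list(cell1, cell2)))
  expect_equal(out$mean_score[out$context == "all"], 0.9)
  expect_equal(out$n[out$context == "all"], 3)
  expect_equal(out$mean_score[out$context == "isolated_in_cell"], 0.9)
  expect_equal(out$n[out$context == "isolated_in_cell"], 1)
  expect_equal(out$mean_score[out$context == "coexisting_in_cell"], 0.9)
  expect_equal(out$n[out$context == "coexisting_in_cell"], 2)
  # no prediction counted twice
  expect_equal(sum(out$n[out$context != "all"]), 3)
  expect_error(mean_box_score(list(preds), context = "isolated_in_cell"), "cells")
})

test_that("tidy and glance expose the report in tabular form", {
  cfg <- generator_config("desk", crystal_classes = "G")
  gts <- generate_annotated(cfg, 2, seed = 33)
  preds <- lapply(gts, function(a) {
    masks <- instance_masks(a, labels = "^crystal")
    tibble::tibble(label = rep("crystal", length(masks)),
                   score = rep(1, length(masks)), mask = masks)
  })
  rep <- evaluate_dataset(preds, gts, 0.7)
  expect_equal(nrow(tidy(rep)), 2)
  g <- glance(rep)
  expect_equal(g$n_images, 2)
  expect_true(all(c("f_measure", "jaccard", "delta_on", "micro_f_measure") %in% names(g)))
})
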