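#' Pixel confusion counts for one image
#'
#' Compares predicted against ground-truth segmentation pixel-wise. The
#' prediction foreground is the union of the predicted instance masks and
#' the ground-truth foreground the union of the ground-truth instance
#' masks (overlapping instances, e.g. crystal clusters, are unioned).
#'
#' @param pred_instances,gt_instances lists of logical masks, a predictions
#'   tibble from [predict.crystal_model()] (column `mask`), or an
#'   [annotated_image()] (its instances are rasterized; see `labels`).
#' @param image_shape `c(n_rows, n_cols)`; required when both inputs are
#'   plain mask lists, otherwise inferred.
#' @param labels regular expression selecting instances by label when an
#'   input carries labels (default `"^crystal"`: crystals only, cell bodies
#'   are context, not target).
#' @return tibble with columns `tp`, `fp`, `fn` (pixel counts).
#' @export
pixel_confusion <- function(pred_instances, gt_instances, image_shape = NULL,
                            labels = "^crystal") {
  shape <- image_shape %||% infer_shape(pred_instances) %||% infer_shape(gt_instances)
  if (is.null(shape)) abort("`image_shape` is required for plain mask lists")
  pred <- as_mask_list(pred_instances, shape, labels)
  gt <- as_mask_list(gt_instances, shape, labels)
  for (m in c(pred, gt)) {
    if (!identical(dim(m), as.integer(shape))) {
      abort("all masks must share `image_shape`")
    }
  }
  pu <- mask_union(pred, shape)
  gu <- mask_union(gt, shape)
  tibble(
    tp = sum(pu & gu),
    fp = sum(pu & !gu),
    fn = sum(!pu & gu)
  )
}

infer_shape <- function(x) {
  if (inherits(x, "annotated_image")) return(c(x$height, x$width))
  if (is.data.frame(x) && "mask" %in% names(x) && nrow(x) > 0L) return(dim(x$mask[[1]]))
  if (is.list(x) && length(x) > 0L && is.matrix(x[[1]])) return(dim(x[[1]]))
  NULL
}

as_mask_list <- function(x, shape, labels = "^crystal") {
  if (inherits(x, "annotated_image")) return(instance_masks(x, labels = labels))
  if (is.data.frame(x)) {
    if ("label" %in% names(x)) x <- x[grepl(labels, x$label), , drop = FALSE]
    if (!"mask" %in% names(x)) {
      if ("polygon" %in% names(x)) return(polygons_to_masks(x$polygon, shape))
      abort("prediction tibble needs a `mask` or `polygon` column")
    }
    return(lapply(x$mask, function(m) m != 0))
  }
  lapply(x, function(m) m != 0)
}

# 0/0 conventions (vectorized over rows of a confusion tibble):
# both sides empty -> perfect (1); exactly one side empty -> 0.
confusion_rates <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  both_empty <- tp + fp + fn == 0
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  j <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), 0)
  tibble(
    precision = ifelse(both_empty, 1, p),
    recall = ifelse(both_empty, 1, r),
    f_measure = ifelse(both_empty, 1, f),
    jaccard = ifelse(both_empty, 1, j)
  )
}

#' Pixel-wise segmentation quality measures
#'
#' With `tp`, `fp`, `fn` the numbers of true-positive, false-positive and
#' false-negative pixels of one image:
#' precision `P = tp / (tp + fp)`, recall `R = tp / (tp + fn)`,
#' F-measure `F = 2PR / (P + R)` (harmonic mean), and Jaccard index
#' `J = tp / (tp + fp + fn)` (intersection over union). All lie in
#' `[0, 1]`, higher is better, and `J = F / (2 - F)` whenever
#' `tp + fp + fn > 0`. Degenerate images: if ground truth and prediction
#' are both empty all four are 1 (a correct negative); if exactly one side
#' is empty all four are 0.
#'
#' @param confusion tibble/data frame with columns `tp`, `fp`, `fn`
#'   (vectorized over rows), as from [pixel_confusion()].
#' @return numeric vector, one value per row.
#' @name pixel-metrics
NULL

#' @rdname pixel-metrics
#' @export
precision <- function(confusion) confusion_rates(confusion)$precision

#' @rdname pixel-metrics
#' @export
recall <- function(confusion) confusion_rates(confusion)$recall

#' @rdname pixel-metrics
#' @export
f_measure <- function(confusion) confusion_rates(confusion)$f_measure

#' @rdname pixel-metrics
#' @export
jaccard <- function(confusion) confusion_rates(confusion)$jaccard

check_count_pairs <- function(counts) {
  counts <- as_tibble(counts)
  if (nrow(counts) == 0L) abort("`counts` must contain at least one image")
  if (!all(c("gt_count", "pred_count") %in% names(counts))) {
    abort("`counts` needs columns `gt_count` and `pred_count`")
  }
  if (any(counts$gt_count < 0) || any(counts$pred_count < 0)) {
    abort("object counts must be non-negative")
  }
  counts
}

#' Object-count error (delta object)
#'
#' The mean absolute difference between the number of ground-truth objects
#' and the number of predicted objects, per image, averaged over the `n`
#' images of a dataset. An object-wise indicator: a missed object and a
#' spurious object on the same image cancel out. Lower is better; not
#' bounded above.
#'
#' @param counts tibble/data frame with one row per image and columns
#'   `gt_count`, `pred_count`.
#' @return non-negative number.
#' @export
delta_object <- function(counts) {
  counts <- check_count_pairs(counts)
  mean(abs(counts$gt_count - counts$pred_count))
}

#' Normalized object-count error (delta object, normalized)
#'
#' Per image, the absolute count difference is divided by the number of
#' ground-truth objects on that image and capped at 1, so images of very
#' different object density contribute equally and the average lies in
#' `[0, 1]` (lower is better). An image with zero ground-truth objects
#' contributes 0 when the prediction is also empty and 1 otherwise.
#'
#' @inheritParams delta_object
#' @return number in `[0, 1]`.
#' @export
delta_object_normalized <- function(counts) {
  counts <- check_count_pairs(counts)
  per_image <- ifelse(
    counts$gt_count == 0,
    ifelse(counts$pred_count == 0, 0, 1),
    pmin(1, abs(counts$gt_count - counts$pred_count) / counts$gt_count)
  )
  mean(per_image)
}

#' Evaluate predictions against ground truth over a dataset
#'
#' Applies the score threshold, computes per-image pixel confusion on
#' instance unions, the four pixel measures, and the per-image object-count
#' terms, then averages arithmetically over images (macro average, the
#' reporting convention used throughout; micro-averaged pixel measures from
#' pooled counts are also included in the summary).
#'
#' @param predictions list with one element per image: a predictions tibble
#'   (columns `label`, `score`, `mask`) as returned by
#'   [predict.crystal_model()], or a list of masks (then scores are taken
#'   as 1).
#' @param ground_truth list of [annotated_image()]s, aligned with
#'   `predictions`.
#' @param score_threshold predictions with `score <` this are discarded
#'   (default 0.7, the reference detector family's default confidence).
#' @param labels regular expression selecting the evaluated classes
#'   (default `"^crystal"`).
#' @return a `metric_report`: list with `per_image` tibble, `averages`
#'   (named list), `n`, `score_threshold`. See [tidy.metric_report()] and
#'   [glance.metric_report()].
#' @export
evaluate_dataset <- function(predictions, ground_truth, score_threshold = 0.7,
                             labels = "^crystal") {
  if (!is.list(predictions) || !is.list(ground_truth) ||
      length(predictions) != length(ground_truth)) {
    abort("`predictions` and `ground_truth` must be lists of equal length, aligned by image")
  }
  if (!is_scalar_number(score_threshold) || score_threshold < 0 || score_threshold > 1) {
    abort("`score_threshold` must be in [0, 1]")
  }
  rows <- lapply(seq_along(predictions), function(i) {
    pred <- predictions[[i]]
    gt <- ground_truth[[i]]
    if (!inherits(gt, "annotated_image")) abort("`ground_truth` must hold annotated_image objects")
    shape <- c(gt$height, gt$width)
    if (is.data.frame(pred) && "score" %in% names(pred)) {
      pred <- pred[pred$score >= score_threshold, , drop = FALSE]
    }
    pred_masks <- as_mask_list(pred, shape, labels)
    gt_masks <- as_mask_list(gt, shape, labels)
    conf <- pixel_confusion(pred_masks, gt_masks, shape)
    rates <- confusion_rates(conf)
    gt_n <- length(gt_masks); pred_n <- length(pred_masks)
    tibble(
      image = i, tp = conf$tp, fp = conf$fp, fn = conf$fn,
      precision = rates$precision, recall = rates$recall,
      f_measure = rates$f_measure, jaccard = rates$jaccard,
      gt_count = gt_n, pred_count = pred_n,
      delta_o = abs(gt_n - pred_n),
      delta_on = if (gt_n == 0) as.numeric(pred_n > 0) else min(1, abs(gt_n - pred_n) / gt_n)
    )
  })
  per_image <- bind_rows(rows)
  averages <- list(
    precision = mean(per_image$precision),
    recall = mean(per_image$recall),
    f_measure = mean(per_image$f_measure),
    jaccard = mean(per_image$jaccard),
    delta_o = delta_object(per_image),
    delta_on = delta_object_normalized(per_image),
    micro_precision = precision(tibble(tp = sum(per_image$tp), fp = sum(per_image$fp), fn = sum(per_image$fn))),
    micro_f_measure = f_measure(tibble(tp = sum(per_image$tp), fp = sum(per_image$fp), fn = sum(per_image$fn))),
    micro_jaccard = jaccard(tibble(tp = sum(per_image$tp), fp = sum(per_image$fp), fn = sum(per_image$fn)))
  )
  structure(
    list(per_image = per_image, averages = averages,
         n = length(predictions), score_threshold = score_threshold),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$averages
  cat(sprintf("<metric_report> %d images @ score threshold %.2f\n", x$n, x$score_threshold))
  cat(sprintf("  mean F = %.2f%%  mean J = %.2f%%  dO = %.3f  dON = %.2f%%\n",
              100 * a$f_measure, 100 * a$jaccard, a$delta_o, 100 * a$delta_on))
  invisible(x)
}

#' Mean objectness score by cellular context
#'
#' In mixed-crystal scenes the per-type pixel metrics are not computed
#' (separate per-type annotation of co-occurring crystals is ambiguous);
#' instead, the mean detection box score is reported for crystals that are
#' the only accepted prediction in their host cell (`isolated_in_cell`)
#' versus those sharing a cell with other accepted predictions
#' (`coexisting_in_cell`). A prediction is assigned to the cell containing
#' its mask centroid; predictions outside every cell are excluded from the
#' per-cell contexts (and counted under `all`).
#'
#' @param predictions list (one element per image) of prediction tibbles
#'   with `score` and `mask` columns, or a single such tibble.
#' @param context `"all"`, `"isolated_in_cell"` or `"coexisting_in_cell"`;
#'   several may be given.
#' @param cells list (aligned with `predictions`) of lists of cell masks,
#'   or of [annotated_image()]s whose `"cell"` instances are used. Required
#'   for the per-cell contexts.
#' @param score_threshold predictions below this score are discarded first.
#' @return tibble with columns `context`, `mean_score`, `n`.
#' @export
mean_box_score <- function(predictions, context = "all", cells = NULL,
                           score_threshold = 0) {
  valid <- c("all", "isolated_in_cell", "coexisting_in_cell")
  if (!all(context %in% valid)) {
    abort(sprintf("`context` must be among: %s", paste(valid, collapse = ", ")))
  }
  if (is.data.frame(predictions)) predictions <- list(predictions)
  if (any(context != "all") && is.null(cells)) {
    abort("per-cell contexts require `cells` (cell masks or annotated images)")
  }
  per_pred <- lapply(seq_along(predictions), function(i) {
    pred <- predictions[[i]]
    pred <- pred[pred$score >= score_threshold, , drop = FALSE]
    if (nrow(pred) == 0L) {
      return(tibble(score = numeric(), cell = integer()))
    }
    cell_of <- rep(NA_integer_, nrow(pred))
    if (!is.null(cells)) {
      cm <- cells[[i]]
      if (inherits(cm, "annotated_image")) cm <- instance_masks(cm, labels = "^cell$")
      for (k in seq_len(nrow(pred))) {
        ctr <- mask_centroid(pred$mask[[k]])
        r <- as.integer(floor(ctr["y"])) + 1L
        c <- as.integer(floor(ctr["x"])) + 1L
        for (ci in seq_along(cm)) {
          m <- cm[[ci]]
          if (r >= 1 && c >= 1 && r <= nrow(m) && c <= ncol(m) && m[r, c]) {
            cell_of[k] <- ci
            break
          }
        }
      }
    }
    tibble(score = pred$score, cell = cell_of, image = i)
  })
  preds <- bind_rows(per_pred)
  out <- lapply(context, function(ctx) {
    if (ctx == "all") {
      sel <- rep(TRUE, nrow(preds))
    } else {
      occupancy <- preds |>
        filter(!is.na(.data$cell)) |>
        dplyr::count(.data$image, .data$cell, name = "k")
      preds2 <- left_join(preds, occupancy, by = c("image", "cell"))
      sel <- !is.na(preds2$cell) &
        if (ctx == "isolated_in_cell") preds2$k == 1 else preds2$k > 1
    }
    tibble(
      context = ctx,
      mean_score = if (any(sel)) mean(preds$score[sel]) else NA_real_,
      n = sum(sel)
    )
  })
  bind_rows(out)
}
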