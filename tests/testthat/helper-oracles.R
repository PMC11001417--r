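# Independent brute-force oracles and shared fixtures.

# Scalar crossing-number point-in-polygon test, written independently of the
# package's vectorized rasterizer: loops pixels and edges one at a time.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(poly, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      mask[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5, poly)
    }
  }
  mask
}

# Random simple polygon: convex hull of random points (always simple).
random_simple_polygon <- function(grid, min_pts = 4, max_pts = 10) {
  repeat {
    n <- sample(min_pts:max_pts, 1)
    pts <- cbind(runif(n, 0, grid), runif(n, 0, grid))
    hull <- grDevices::chull(pts)
    if (length(hull) >= 3) return(pts[hull, , drop = FALSE])
  }
}

# Pixel-enumeration confusion oracle over a pair of masks.
oracle_confusion <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && gt[i]) tp <- tp + 1L
    else if (pred[i] && !gt[i]) fp <- fp + 1L
    else if (!pred[i] && gt[i]) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Shared expensive fixtures, computed once per test session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Easy-regime learning run: train on 10 high-contrast images, score the mean
# F-measure on 20 held-out images. Used by the model unit tests and the
# learning-sanity acceptance check.
easy_learning_f <- function(seed) {
  cached(paste0("easy_f_", seed), {
    cfg <- generator_config("easy")
    train_set <- generate_annotated(cfg, 10, seed = seed)
    test_set <- generate_annotated(cfg, 20, seed = seed + 5000L)
    fit <- train_model(init_model("ref", seed = seed), train_set,
                       training_protocol("primary", seed = seed))
    preds <- lapply(test_set, function(a) predict(fit$model, a, score_threshold = 0.7))
    list(
      fit = fit,
      test_set = test_set,
      report = evaluate_dataset(preds, test_set, score_threshold = 0.7)
    )
  })
}

desk_trend_run <- function(seed, full = FALSE) {
  cached(paste0("desk_trend_", seed, "_", full), {
    plan <- build_plan("desk", seed = seed)
    run_plan(plan, rows = if (full) NULL else c(3L, 4L, 12L, 13L))
  })
}
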