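#' Build the training-strategy experiment plan
#'
#' Builds the 19-row training matrix of the screening study the package
#' emulates:
#' single-target primary trainings on 10/30/50 images of each target
#' (rows 1-3 and 10-12), incremental secondary trainings of the 50-image
#' primaries on 10/30/50 images of the other target at learning rates 1e-3
#' and 1e-4 (rows 4-9 and 13-18), and the single-stage combined training on
#' 50 + 50 images (row 19). Every row is evaluated on both single-target
#' test sets.
#'
#' `scale = "full"` keeps the study-scale set sizes (10/30/50 training
#' images, 150-image test sets); `scale = "desk"` substitutes small counts
#' (4/8/12 training, 20 test) that preserve the row structure and run on a
#' CPU in minutes. Smaller training subsets are nested within larger ones.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seed global seed; all dataset and training randomness derives
#'   from it through fixed substreams.
#' @param backend_id segmentation backend (see [init_model()]).
#' @param score_threshold detection confidence used for evaluation.
#' @return an `experiment_plan`: list with the `rows` tibble, the scale,
#'   the per-target generator configs, the test-set size and the seed.
#' @export
build_plan <- function(scale = c("desk", "full"), seed = 1,
                       backend_id = "ref", score_threshold = 0.7) {
  scale <- match.arg(scale)
  n_map <- if (scale == "full") {
    c("10" = 10L, "30" = 30L, "50" = 50L)
  } else {
    c("10" = 4L, "30" = 8L, "50" = 12L)
  }
  test_n <- if (scale == "full") 150L else 20L
  secondary_block <- function(primary, secondary) {
    tidyr::expand_grid(n = c(10L, 30L, 50L), lr = c(1e-3, 1e-4)) |>
      mutate(primary_target = primary, primary_n = 50L,
             secondary_target = secondary, secondary_n = .data$n,
             secondary_lr = .data$lr, combined = FALSE) |>
      select(-"n", -"lr")
  }
  rows <- bind_rows(
    tibble(primary_target = "G", primary_n = c(10L, 30L, 50L),
           secondary_target = NA_character_, secondary_n = NA_integer_,
           secondary_lr = NA_real_, combined = FALSE),
    secondary_block("G", "H"),
    tibble(primary_target = "H", primary_n = c(10L, 30L, 50L),
           secondary_target = NA_character_, secondary_n = NA_integer_,
           secondary_lr = NA_real_, combined = FALSE),
    secondary_block("H", "G"),
    tibble(primary_target = "G+H", primary_n = 100L,
           secondary_target = NA_character_, secondary_n = NA_integer_,
           secondary_lr = NA_real_, combined = TRUE)
  ) |>
    mutate(row_id = row_number(), .before = 1) |>
    mutate(label = strategy_label(.data$primary_target, .data$primary_n,
                                  .data$secondary_target, .data$secondary_n,
                                  .data$secondary_lr, .data$combined))
  structure(
    list(
      rows = rows, scale = scale, seed = as.integer(seed),
      n_map = n_map, test_n = test_n, backend_id = backend_id,
      score_threshold = score_threshold,
      config_G = generator_config(if (scale == "full") "full" else "desk",
                                  crystal_classes = "G"),
      config_H = generator_config(if (scale == "full") "full" else "desk",
                                  crystal_classes = "H")
    ),
    class = "experiment_plan"
  )
}

strategy_label <- function(pt, pn, st, sn, slr, combined) {
  mapply(function(pt, pn, st, sn, slr, combined) {
    if (combined) return("H_50 + G_50 (LR = 1e-03)")
    if (is.na(st)) return(sprintf("%s_%d > -", pt, pn))
    sprintf("%s_%d > %s_%d (LR = %s)", pt, pn, st, sn,
            format(slr, scientific = TRUE))
  }, pt, pn, st, sn, slr, combined, USE.NAMES = FALSE)
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> %d rows, scale `%s`, seed %d, backend `%s`\n",
              nrow(x$rows), x$scale, x$seed, x$backend_id))
  invisible(x)
}

#' Run an experiment plan
#'
#' Generates the per-target training pools and test sets from seeded
#' substreams of the plan seed (test sets disjoint from training pools by
#' construction), executes each row's training strategy, and evaluates the
#' resulting model on both test sets. The two 50-image primary models are
#' trained once and shared by their secondary rows, mirroring the study
#' design (the secondary trainings continue the same primary model). A row
#' failure is recorded and the remaining rows proceed.
#'
#' @param plan an [build_plan()] result.
#' @param rows optional integer vector restricting execution to a subset of
#'   row ids (training pools and test sets are unchanged).
#' @param verbose print one line per row.
#' @return an `experiment_result`: the plan plus a `results` tibble with,
#'   per row, the mean F/J/delta-O-normalized on each target's test set and
#'   the full `metric_report`s and training logs as list-columns.
#' @export
run_plan <- function(plan, rows = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  rows <- rows %||% plan$rows$row_id
  seed <- plan$seed
  max_train <- max(plan$n_map)
  pools <- list(
    G = generate_annotated(plan$config_G, max_train, child_seed(seed, 101L)),
    H = generate_annotated(plan$config_H, max_train, child_seed(seed, 102L))
  )
  tests <- list(
    G = generate_annotated(plan$config_G, plan$test_n, child_seed(seed, 201L)),
    H = generate_annotated(plan$config_H, plan$test_n, child_seed(seed, 202L))
  )
  # primary 50-image models are shared across their secondary rows
  primary_cache <- new.env(parent = emptyenv())
  train_primary <- function(target, n_images, protocol_seed) {
    key <- sprintf("%s_%d", target, n_images)
    if (!exists(key, envir = primary_cache)) {
      model <- init_model(plan$backend_id, seed = child_seed(seed, 300L))
      fit <- train_model(model, pools[[target]][seq_len(n_images)],
                         training_protocol("primary", seed = protocol_seed))
      assign(key, fit, envir = primary_cache)
    }
    get(key, envir = primary_cache)
  }
  out <- vector("list", length(rows))
  for (ri in seq_along(rows)) {
    row <- plan$rows[plan$rows$row_id == rows[ri], ]
    res <- tryCatch({
      logs <- list()
      if (row$combined) {
        half <- plan$n_map[["50"]]
        combined_set <- c(pools$G[seq_len(half)], pools$H[seq_len(half)])
        fit <- train_model(init_model(plan$backend_id, seed = child_seed(seed, 300L)),
                           combined_set,
                           training_protocol("combined", seed = child_seed(seed, 400L + row$row_id)))
        model <- fit$model; logs <- list(fit$log)
      } else {
        pn <- plan$n_map[[as.character(row$primary_n)]]
        fit <- train_primary(row$primary_target, pn, child_seed(seed, 400L + row$primary_n))
        model <- fit$model; logs <- list(fit$log)
        if (!is.na(row$secondary_target)) {
          sn <- plan$n_map[[as.character(row$secondary_n)]]
          fit2 <- train_model(model, pools[[row$secondary_target]][seq_len(sn)],
                              training_protocol("secondary",
                                                learning_rate = row$secondary_lr,
                                                seed = child_seed(seed, 500L + row$row_id)))
          model <- fit2$model; logs <- c(logs, list(fit2$log))
        }
      }
      report_for <- function(target) {
        preds <- lapply(tests[[target]],
                        function(a) predict(model, a, plan$score_threshold))
        evaluate_dataset(preds, tests[[target]], plan$score_threshold)
      }
      rep_H <- report_for("H"); rep_G <- report_for("G")
      if (verbose) {
        cat(sprintf("row %2d %-28s F(H) %5.1f%%  F(G) %5.1f%%\n", row$row_id, row$label,
                    100 * rep_H$averages$f_measure, 100 * rep_G$averages$f_measure))
      }
      tibble(
        row_id = row$row_id, label = row$label, status = "ok",
        f_H = rep_H$averages$f_measure, f_G = rep_G$averages$f_measure,
        j_H = rep_H$averages$jaccard, j_G = rep_G$averages$jaccard,
        delta_on_H = rep_H$averages$delta_on, delta_on_G = rep_G$averages$delta_on,
        delta_o_H = rep_H$averages$delta_o, delta_o_G = rep_G$averages$delta_o,
        report_H = list(rep_H), report_G = list(rep_G),
        logs = list(logs), lineage = list(model$lineage)
      )
    }, error = function(e) {
      tibble(row_id = row$row_id, label = row$label,
             status = paste("error:", conditionMessage(e)),
             f_H = NA_real_, f_G = NA_real_, j_H = NA_real_, j_G = NA_real_,
             delta_on_H = NA_real_, delta_on_G = NA_real_,
             delta_o_H = NA_real_, delta_o_G = NA_real_,
             report_H = list(NULL), report_G = list(NULL),
             logs = list(NULL), lineage = list(NULL))
    })
    out[[ri]] <- res
  }
  structure(
    list(plan = plan, results = bind_rows(out)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d/%d rows, scale `%s`, seed %d\n",
              sum(x$results$status == "ok"), nrow(x$plan$rows),
              x$plan$scale, x$plan$seed))
  print(select(x$results, "row_id", "label", "f_H", "f_G", "delta_on_H", "delta_on_G"))
  invisible(x)
}

#' Write the strategy-comparison table
#'
#' Tab-separated table in the screening study's layout: one row per training
#' strategy with the average F-measure, Jaccard index and normalized
#' object-count error per target, as percentages with 2 decimals. Higher
#' F/J and lower normalized object error indicate better performance. A
#' `#`-prefixed provenance header records scale, seed, backend and
#' threshold. Rows that failed (or were not run) appear with empty metric
#' cells. Re-rendering the same result reproduces the file byte-identically.
#'
#' @param result an [run_plan()] result (complete or partial).
#' @param out output file path.
#' @return `out`, invisibly.
#' @export
report_table <- function(result, out) {
  stopifnot(inherits(result, "experiment_result"))
  plan <- result$plan
  header <- c(
    "# cellcryst strategy comparison",
    sprintf("# scale: %s  seed: %d  backend: %s  score_threshold: %g",
            plan$scale, plan$seed, plan$backend_id, plan$score_threshold),
    sprintf("# training images per nominal 10/30/50: %s  test images per target: %d",
            paste(plan$n_map, collapse = "/"), plan$test_n)
  )
  pct <- function(x) ifelse(is.na(x), "", sprintf("%.2f", 100 * x))
  full <- left_join(select(plan$rows, "row_id", "label"),
                    select(result$results, -"label"), by = "row_id")
  body <- tibble(
    No. = full$row_id,
    `Training set (primary > secondary)` = full$label,
    `F-measure (%) target H` = pct(full$f_H),
    `F-measure (%) target G` = pct(full$f_G),
    `Jaccard (%) target H` = pct(full$j_H),
    `Jaccard (%) target G` = pct(full$j_G),
    `dON (%) target H` = pct(full$delta_on_H),
    `dON (%) target G` = pct(full$delta_on_G)
  )
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(body), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Box-score analysis on mixed-crystal scenes
#'
#' Runs a trained model over scenes containing both crystal classes (the
#' co-infection scenario) and summarizes the detection box scores by
#' cellular context: crystals detected as the only prediction in their host
#' cell versus crystals coexisting with other predictions in the same cell.
#' Per-type pixel metrics are deliberately not computed for mixed scenes
#' (the per-type annotation of co-occurring crystals is ambiguous).
#'
#' @param model a trained `crystal_model`.
#' @param mixed_dataset list of [annotated_image()]s generated with
#'   `crystal_classes = "mixed"`; the `"cell"` instances must be present.
#' @param score_threshold detection confidence (default 0.7).
#' @return tibble with one row per context (`all`, `isolated_in_cell`,
#'   `coexisting_in_cell`): `mean_score` and prediction count `n`.
#' @export
mixed_crystal_analysis <- function(model, mixed_dataset, score_threshold = 0.7) {
  stopifnot(inherits(model, "crystal_model"))
  has_cells <- vapply(mixed_dataset,
                      function(a) any(a$instances$label == "cell"), logical(1))
  if (!all(has_cells)) {
    abort("mixed-crystal analysis requires cell instances in every image")
  }
  preds <- lapply(mixed_dataset, function(a) predict(model, a, score_threshold))
  mean_box_score(preds,
                 context = c("all", "isolated_in_cell", "coexisting_in_cell"),
                 cells = mixed_dataset, score_threshold = score_threshold)
}
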