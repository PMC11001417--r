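#' Broom-style tidiers
#'
#' `tidy()` returns the per-unit breakdown of a result object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x a `metric_report`, `crystal_model` or `experiment_result`.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.metric_report <- function(x, ...) x$per_image

#' @rdname tidiers
#' @export
glance.metric_report <- function(x, ...) {
  as_tibble(x$averages) |>
    mutate(n_images = x$n, score_threshold = x$score_threshold)
}

#' @rdname tidiers
#' @export
tidy.crystal_model <- function(x, ...) x$lineage

#' @rdname tidiers
#' @export
glance.crystal_model <- function(x, ...) {
  tibble(backend_id = x$backend_id,
         classes = paste(x$class_set, collapse = ","),
         n_training_stages = nrow(x$lineage),
         n_parameters = length(x$weights))
}

#' @rdname tidiers
#' @export
tidy.experiment_result <- function(x, ...) {
  select(x$results, "row_id", "label", "status",
         "f_H", "f_G", "j_H", "j_G", "delta_on_H", "delta_on_G",
         "delta_o_H", "delta_o_G")
}

#' @rdname tidiers
#' @export
glance.experiment_result <- function(x, ...) {
  ok <- x$results$status == "ok"
  tibble(
    scale = x$plan$scale, seed = x$plan$seed, backend_id = x$plan$backend_id,
    rows_ok = sum(ok), rows_total = nrow(x$plan$rows),
    best_f_H = if (any(ok)) max(x$results$f_H[ok]) else NA_real_,
    best_f_G = if (any(ok)) max(x$results$f_G[ok]) else NA_real_
  )
}
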