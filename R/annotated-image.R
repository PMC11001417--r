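#' Construct an annotated image
#'
#' The in-memory form of one microscopy image plus its per-instance ground
#' truth: each instance is a labelled polygon outline (class `"crystal_G"`,
#' `"crystal_H"`, `"cell"`, or any other label passed through verbatim).
#' Binary masks are derived on demand with [instance_masks()]; storing
#' polygons keeps large images cheap and mirrors how annotation tools save
#' ground truth.
#'
#' @param image numeric matrix (grayscale, values in `[0, 1]`) or
#'   `H x W x 3` array, or `NULL` when only the annotation is known.
#' @param instances tibble with columns `label` (character) and `polygon`
#'   (list of two-column vertex matrices, 0-based pixel coordinates);
#'   an optional `score` column is kept (used for predictions exported as
#'   annotations) and an optional `group_id` column marks cluster membership.
#' @param height,width image dimensions in pixels; inferred from `image`
#'   when omitted.
#' @param pixel_pitch_um physical size of one pixel in micrometres
#'   (`NA` when unknown).
#' @param provenance free-text origin (generator seed, source file path).
#' @return object of class `annotated_image`.
#' @export
annotated_image <- function(image = NULL, instances = empty_instances(),
                            height = NULL, width = NULL,
                            pixel_pitch_um = NA_real_, provenance = NA_character_) {
  if (!is.null(image)) {
    height <- height %||% dim(image)[1]
    width <- width %||% dim(image)[2]
    if (dim(image)[1] != height || dim(image)[2] != width) {
      abort("image dimensions disagree with `height`/`width`")
    }
  }
  if (is.null(height) || is.null(width)) {
    abort("`height` and `width` are required when `image` is NULL")
  }
  instances <- as_tibble(instances)
  if (!all(c("label", "polygon") %in% names(instances))) {
    abort("`instances` must have columns `label` and `polygon`")
  }
  instances$polygon <- lapply(instances$polygon, as_polygon)
  structure(
    list(image = image, instances = instances,
         height = as.integer(height), width = as.integer(width),
         pixel_pitch_um = as.numeric(pixel_pitch_um),
         provenance = provenance),
    class = "annotated_image"
  )
}

empty_instances <- function() {
  tibble(label = character(), polygon = list())
}

#' @export
print.annotated_image <- function(x, ...) {
  counts <- table(x$instances$label)
  cat(sprintf("<annotated_image> %d x %d px", x$height, x$width))
  if (!is.na(x$pixel_pitch_um)) {
    cat(sprintf(" (%.4f um/px)", x$pixel_pitch_um))
  }
  cat("\n")
  if (nrow(x$instances) == 0L) {
    cat("  no instances\n")
  } else {
    cat("  instances:", paste(sprintf("%s x%d", names(counts), counts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rasterize the instances of an annotated image
#'
#' @param annotated an [annotated_image()].
#' @param labels optional regular expression; only instances whose label
#'   matches are rasterized (e.g. `"^crystal"`).
#' @return list of logical masks, one per (selected) instance, each of the
#'   image's shape.
#' @export
instance_masks <- function(annotated, labels = NULL) {
  stopifnot(inherits(annotated, "annotated_image"))
  inst <- annotated$instances
  if (!is.null(labels)) inst <- inst[grepl(labels, inst$label), , drop = FALSE]
  polygons_to_masks(inst$polygon, c(annotated$height, annotated$width))
}

#' Convert polygons to binary instance masks
#'
#' One mask per polygon; a pixel is foreground iff its center lies inside
#' the polygon under the even-odd rule (see [rasterize_polygon()]).
#'
#' @param polygons list of two-column vertex matrices (0-based pixel
#'   coordinates); polygons may extend beyond the frame (clipped).
#' @param image_shape integer vector `c(n_rows, n_cols)`.
#' @return list of logical matrices.
#' @export
polygons_to_masks <- function(polygons, image_shape) {
  lapply(polygons, rasterize_polygon, shape = image_shape)
}

# union of a list of logical masks
mask_union <- function(masks, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (m in masks) out <- out | m
  out
}
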