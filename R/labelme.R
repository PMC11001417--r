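#' Read a Labelme-dialect polygon annotation
#'
#' Parses the JSON dialect written by the Labelme annotation tool (and by
#' [write_labelme()]): top-level keys `shapes`, `imageHeight`, `imageWidth`;
#' each shape has a `label` and a list of `points` in (x, y) pixel
#' coordinates, 0-based, origin at the top-left corner. Files with and
#' without a `version` key are both accepted. A `score` field on a shape
#' (written for model predictions) is preserved.
#'
#' @param path annotation file path.
#' @param read_image if `TRUE` (default) and the referenced `imagePath`
#'   exists next to the annotation, the image is loaded too.
#' @return an [annotated_image()]; `image` is `NULL` when unavailable.
#' @export
read_labelme <- function(path, read_image = TRUE) {
  if (!file.exists(path)) abort(sprintf("annotation file does not exist: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("shapes", "imageHeight", "imageWidth")) {
    if (is.null(doc[[key]])) {
      abort(sprintf("not a Labelme annotation: missing key `%s` in %s", key, path),
            class = "cellcryst_format_error")
    }
  }
  shapes <- doc$shapes
  inst <- tibble(
    label = vapply(shapes, function(s) {
      if (is.null(s$label)) abort(sprintf("shape without `label` in %s", path),
                                  class = "cellcryst_format_error")
      as.character(s$label)
    }, character(1)),
    polygon = lapply(shapes, function(s) {
      if (is.null(s$points)) abort(sprintf("shape without `points` in %s", path),
                                   class = "cellcryst_format_error")
      pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
      as_polygon(pts)
    }),
    score = vapply(shapes, function(s) {
      if (is.null(s$score)) NA_real_ else as.numeric(s$score)
    }, numeric(1)),
    group_id = vapply(shapes, function(s) {
      if (is.null(s$group_id)) NA_integer_ else as.integer(s$group_id)
    }, integer(1))
  )
  bad <- which(!vapply(inst$polygon, polygon_is_simple, logical(1)))
  if (length(bad) > 0L) {
    warn(sprintf("self-intersecting polygon(s) at shape index %s in %s; rasterized with the even-odd rule",
                 paste(bad, collapse = ", "), path))
  }
  img <- NULL
  if (read_image && !is.null(doc$imagePath) && nzchar(doc$imagePath)) {
    img_path <- file.path(dirname(path), doc$imagePath)
    if (file.exists(img_path)) img <- read_image_file(img_path)
  }
  pitch <- if (is.null(doc$pixelPitchUm)) NA_real_ else as.numeric(doc$pixelPitchUm)
  annotated_image(
    image = img, instances = inst,
    height = as.integer(doc$imageHeight), width = as.integer(doc$imageWidth),
    pixel_pitch_um = pitch, provenance = path
  )
}

#' Write an annotated image as a Labelme-dialect JSON file
#'
#' The output is readable by [read_labelme()] and by the public Labelme
#' application. Instances are written as polygon shapes; labels are
#' preserved verbatim. Output bytes are deterministic for identical input.
#'
#' @param annotated an [annotated_image()]. Instances must carry polygons
#'   (predictions holding masks are traced with [mask_to_polygon()] first).
#' @param path output file path.
#' @param image_path value for the `imagePath` key (relative path of the
#'   paired image); defaults to none.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(annotated, path, image_path = "") {
  stopifnot(inherits(annotated, "annotated_image"))
  inst <- annotated$instances
  shapes <- lapply(seq_len(nrow(inst)), function(i) {
    poly <- inst$polygon[[i]]
    s <- list(
      label = jsonlite::unbox(inst$label[i]),
      points = lapply(seq_len(nrow(poly)), function(k) c(poly[k, 1], poly[k, 2])),
      group_id = if ("group_id" %in% names(inst) && !is.na(inst$group_id[i])) {
        jsonlite::unbox(inst$group_id[i])
      } else NULL,
      shape_type = jsonlite::unbox("polygon"),
      flags = stats::setNames(list(), character(0))
    )
    if ("score" %in% names(inst) && !is.na(inst$score[i])) {
      s$score <- jsonlite::unbox(round(inst$score[i], 6))
    }
    s
  })
  doc <- list(
    version = jsonlite::unbox("5.2.1"),
    flags = stats::setNames(list(), character(0)),
    shapes = shapes,
    imagePath = jsonlite::unbox(image_path),
    imageData = NULL,
    imageHeight = jsonlite::unbox(annotated$height),
    imageWidth = jsonlite::unbox(annotated$width)
  )
  if (!is.na(annotated$pixel_pitch_um)) {
    doc$pixelPitchUm <- jsonlite::unbox(annotated$pixel_pitch_um)
  }
  json <- jsonlite::toJSON(doc, null = "null", digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# Image file I/O --------------------------------------------------------------

#' Read an image file (PNG or TIFF, 8-bit grayscale or RGB)
#' @param path image path.
#' @return numeric matrix (grayscale) or `H x W x 3` array, values in `[0, 1]`.
#' @export
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF requires the `tiff` package")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format `%s` (PNG or TIFF expected)", ext))
  )
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3] else img <- as_gray(img)
  img
}

#' Write an image file (PNG, 8-bit)
#' @param img numeric matrix or `H x W x 3` array with values in `[0, 1]`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image_file <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

# Dataset manifests ------------------------------------------------------------

#' Write a dataset manifest
#'
#' Tab-separated file listing image/annotation pairs with per-class instance
#' counts; a `#`-prefixed header records the seed and config fingerprint.
#'
#' @param manifest tibble with columns `image_path`, `annotation_path`,
#'   `n_crystal_G`, `n_crystal_H`, `n_cell`, `seed`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  fp <- attr(manifest, "config_fingerprint") %||% ""
  seed <- attr(manifest, "seed") %||% NA
  header <- c(
    sprintf("# cellcryst dataset manifest"),
    sprintf("# seed: %s", seed),
    sprintf("# config_fingerprint: %s", fp)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(manifest), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest written by [write_manifest()]
#' @param path manifest path.
#' @param check_paths verify that all referenced files exist (default `TRUE`).
#' @return tibble of class `dataset_manifest`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  manifest <- as_tibble(df)
  if (nrow(manifest) < 1L) abort("manifest contains no records")
  base <- dirname(path)
  if (check_paths) {
    paths <- file.path(base, c(manifest$image_path, manifest$annotation_path))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      abort(sprintf("manifest references missing files: %s",
                    paste(utils::head(missing, 3), collapse = ", ")))
    }
  }
  seed_line <- grep("^# seed:", header, value = TRUE)
  fp_line <- grep("^# config_fingerprint:", header, value = TRUE)
  attr(manifest, "seed") <- if (length(seed_line)) {
    suppressWarnings(as.integer(sub("^# seed:\\s*", "", seed_line[1])))
  } else NA_integer_
  attr(manifest, "config_fingerprint") <- if (length(fp_line)) {
    sub("^# config_fingerprint:\\s*", "", fp_line[1])
  } else NA_character_
  attr(manifest, "base_dir") <- base
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

# Load the annotated images referenced by a manifest into memory.
load_manifest_images <- function(manifest) {
  base <- attr(manifest, "base_dir") %||% "."
  lapply(seq_len(nrow(manifest)), function(i) {
    ann <- read_labelme(file.path(base, manifest$annotation_path[i]), read_image = FALSE)
    ann$image <- read_image_file(file.path(base, manifest$image_path[i]))
    ann
  })
}
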