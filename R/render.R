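#' Render a sampled scene to an annotated image
#'
#' Produces the bright-field-like intensity image at full acquisition
#' resolution together with one ground-truth instance per cell and per
#' crystal. Cells render as translucent ellipses with a darker rim.
#' Crystals render at higher contrast than cells with a strong dark edge
#' band; the interior contrast is signed per class (large rods refract
#' light and appear slightly bright with pronounced edges, the smaller
#' hexagonal crystals appear uniformly dark), reflecting how the two
#' morphologies differ under bright-field illumination. Gaussian sensor
#' noise and blur are applied. The physical
#' pixel pitch is `field_of_view_um / full_resolution_px`. Deterministic
#' for a fixed scene (the render noise stream is derived from the scene
#' seed).
#'
#' @param scene a `crystal_scene` from [sample_scene()].
#' @return an [annotated_image()] at full resolution with instance labels
#'   `"cell"`, `"crystal_G"`, `"crystal_H"`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "crystal_scene"))
  cfg <- scene$config
  px <- cfg$full_resolution_px
  pitch <- pixel_pitch(cfg, "full")
  with_seed(child_seed(scene$seed, 99991L), {
    img <- matrix(rnorm(px * px, cfg$background_mean, cfg$background_sd), px, px)
    cell_polys <- lapply(seq_len(nrow(scene$cells)), function(i) {
      cell <- scene$cells[i, ]
      ellipse_polygon(cell$cx, cell$cy, cell$a, cell$b, cell$orientation)
    })
    for (i in seq_along(cell_polys)) {
      poly <- cell_polys[[i]]
      img <- paint_polygon(img, poly, -cfg$cell_contrast * runif(1, 0.7, 1.1))
      # darker rim: band between the ellipse and a slightly shrunk copy
      img <- paint_ring(img, poly, scale_about_centroid(poly, 0.90), -cfg$rim_contrast)
    }
    for (i in seq_len(nrow(scene$crystals))) {
      poly <- scene$crystals$polygon[[i]]
      interior <- if (scene$crystals$crystal_class[i] == "G") cfg$g_contrast else cfg$h_contrast
      img <- paint_polygon(img, poly, interior * runif(1, 0.85, 1.1))
      img <- paint_ring(img, poly, scale_about_centroid(poly, 0.80), -cfg$edge_contrast)
    }
    if (cfg$blur_sigma > 0) {
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = cfg$blur_sigma))
    }
    img <- clamp01(img)
    instances <- bind_rows(
      tibble(label = rep("cell", length(cell_polys)), polygon = cell_polys,
             group_id = rep(NA_integer_, length(cell_polys))),
      tibble(label = paste0("crystal_", scene$crystals$crystal_class),
             polygon = scene$crystals$polygon,
             group_id = scene$crystals$cluster_id)
    )
    annotated_image(
      image = img, instances = instances,
      pixel_pitch_um = pitch,
      provenance = sprintf("synthetic scene seed %d", scene$seed)
    )
  })
}

# add `delta` to the pixels inside `poly`, touching only the bounding box
paint_polygon <- function(img, poly, delta) {
  m <- rasterize_polygon(poly, dim(img))
  img[m] <- img[m] + delta
  img
}

paint_ring <- function(img, outer, inner, delta) {
  mo <- rasterize_polygon(outer, dim(img))
  mi <- rasterize_polygon(inner, dim(img))
  band <- mo & !mi
  img[band] <- img[band] + delta
  img
}

#' Generate annotated images in memory
#'
#' Samples and renders `n_images` scenes, each from its own seed substream
#' of `seed` (so earlier images do not change when `n_images` grows), and
#' downscales them to the configured output resolution.
#'
#' @param config a [generator_config()].
#' @param n_images number of images (>= 1).
#' @param seed root seed.
#' @return list of [annotated_image()]s at `output_resolution_px`.
#' @export
generate_annotated <- function(config, n_images, seed) {
  config <- validate_generator_config(unclass(config))
  n_images <- as.integer(n_images)
  if (n_images < 1L) abort("`n_images` must be >= 1")
  lapply(seq_len(n_images), function(i) {
    scene <- sample_scene(config, child_seed(seed, i))
    ann <- render_scene(scene)
    if (config$output_resolution_px != config$full_resolution_px) {
      ann <- suppressWarnings(resize_annotated(ann, config$output_resolution_px))
    }
    ann
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG images at the configured output resolution with
#' paired Labelme-dialect annotation files and a tab-separated manifest.
#' Regenerating with the same `(config, n_images, seed)` reproduces the
#' files byte-identically.
#'
#' @param config a [generator_config()].
#' @param n_images number of image/annotation pairs (>= 1).
#' @param seed root seed.
#' @param out_dir output directory (created if missing).
#' @return the manifest tibble (class `dataset_manifest`), invisibly
#'   pointing at `file.path(out_dir, "manifest.tsv")`.
#' @export
generate_dataset <- function(config, n_images, seed, out_dir) {
  config <- validate_generator_config(unclass(config))
  n_images <- as.integer(n_images)
  if (n_images < 1L) abort("`n_images` must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory: %s", out_dir))
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    s <- child_seed(seed, i)
    scene <- sample_scene(config, s)
    ann <- render_scene(scene)
    if (config$output_resolution_px != config$full_resolution_px) {
      ann <- suppressWarnings(resize_annotated(ann, config$output_resolution_px))
    }
    img_name <- sprintf("img_%04d.png", i)
    ann_name <- sprintf("img_%04d.json", i)
    write_image_file(ann$image, file.path(out_dir, img_name))
    write_labelme(ann, file.path(out_dir, ann_name), image_path = img_name)
    records[[i]] <- tibble(
      image_path = img_name, annotation_path = ann_name,
      n_crystal_G = sum(ann$instances$label == "crystal_G"),
      n_crystal_H = sum(ann$instances$label == "crystal_H"),
      n_cell = sum(ann$instances$label == "cell"),
      seed = s
    )
  }
  manifest <- bind_rows(records)
  attr(manifest, "seed") <- as.integer(seed)
  attr(manifest, "config_fingerprint") <- config_fingerprint(config)
  attr(manifest, "base_dir") <- out_dir
  class(manifest) <- c("dataset_manifest", class(manifest))
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

config_fingerprint <- function(config) {
  flat <- unlist(unclass(config))
  content_hash(paste(names(flat), format(flat, digits = 12), sep = "="))
}
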