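#' Resize an annotated image
#'
#' Applies the acquisition pipeline's downscaling step: the image is
#' resampled with a bilinear filter, instance polygons are scaled by
#' `target / original` per axis, and the physical pixel pitch is rescaled
#' accordingly. Instance masks, being derived from polygons on demand,
#' stay binary by construction; [resize_mask()] offers the equivalent
#' nearest-neighbor resampling for standalone masks.
#'
#' Resizing never drops an instance: if a scaled instance would rasterize
#' below one pixel of area, it is kept (polygon intact) and a warning is
#' emitted.
#'
#' @param annotated an [annotated_image()] with a non-`NULL` image or known
#'   dimensions.
#' @param target target size in pixels (square output `target x target`);
#'   non-square inputs are scaled independently per axis with a warning.
#' @return a resized [annotated_image()].
#' @export
resize_annotated <- function(annotated, target) {
  stopifnot(inherits(annotated, "annotated_image"))
  target <- as.integer(target)
  if (target < 16L) abort("`target` must be at least 16 px")
  h <- annotated$height; w <- annotated$width
  if (h != w) warn("non-square input: axes scaled independently")
  if (target == h && target == w) return(annotated)
  sy <- target / h
  sx <- target / w
  img <- annotated$image
  if (!is.null(img)) {
    if (is.matrix(img)) {
      img <- eb_resize(img, target, target)
    } else {
      img <- simplify2array(lapply(seq_len(dim(img)[3]),
                                   function(k) eb_resize(img[, , k], target, target)))
    }
  }
  inst <- annotated$instances
  inst$polygon <- lapply(inst$polygon, scale_polygon, sx = sx, sy = sy)
  tiny <- vapply(inst$polygon, polygon_area, numeric(1)) < 1
  if (any(tiny)) {
    warn(sprintf("%d instance(s) fall below one pixel of area after resizing (kept as sub-pixel polygons)",
                 sum(tiny)))
  }
  annotated_image(
    image = img, instances = inst, height = target, width = target,
    pixel_pitch_um = annotated$pixel_pitch_um / mean(c(sx, sy)),
    provenance = annotated$provenance
  )
}

# bilinear resize of a matrix via EBImage; w maps to rows, h to columns
eb_resize <- function(mat, new_nrow, new_ncol) {
  out <- EBImage::resize(EBImage::Image(mat), w = new_nrow, h = new_ncol)
  EBImage::imageData(out)
}

#' Nearest-neighbor resize of a binary mask
#'
#' Each output pixel takes the value of the input pixel whose center is
#' nearest to the output pixel center mapped back into input coordinates.
#' Keeps masks strictly binary (no interpolation, no re-threshold).
#'
#' @param mask logical or 0/1 matrix.
#' @param target target size (square `target x target`).
#' @return logical matrix.
#' @export
resize_mask <- function(mask, target) {
  target <- as.integer(target)
  nr <- nrow(mask); nc <- ncol(mask)
  src_r <- pmin(nr, pmax(1L, as.integer(ceiling((seq_len(target) - 0.5) * nr / target))))
  src_c <- pmin(nc, pmax(1L, as.integer(ceiling((seq_len(target) - 0.5) * nc / target))))
  (mask != 0)[src_r, src_c, drop = FALSE]
}
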