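#' Polygon geometry and rasterization
#'
#' Polygons are numeric matrices with two columns, `x` and `y`, holding
#' vertices in 0-based pixel coordinates: the pixel in row `r`, column `c`
#' of an image matrix (1-based R indexing) covers the unit square
#' `[c-1, c] x [r-1, r]` and has its center at `(c - 0.5, r - 0.5)`.
#' This matches the coordinate convention of the Labelme annotation dialect
#' (origin at the top-left corner, `x` along columns, `y` along rows).
#'
#' @name polygon-geometry
NULL

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || !is.numeric(p)) {
    abort("a polygon must be a numeric matrix with >= 3 rows and 2 columns (x, y)")
  }
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

#' Signed and absolute polygon area (shoelace formula)
#' @param poly two-column vertex matrix.
#' @return absolute area in squared pixels.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  c(mean(poly[, 1]), mean(poly[, 2]))
}

translate_polygon <- function(poly, dx, dy) {
  poly <- as_polygon(poly)
  poly[, 1] <- poly[, 1] + dx
  poly[, 2] <- poly[, 2] + dy
  poly
}

scale_polygon <- function(poly, sx, sy = sx) {
  poly <- as_polygon(poly)
  poly[, 1] <- poly[, 1] * sx
  poly[, 2] <- poly[, 2] * sy
  poly
}

# Shrink/grow a polygon about its centroid (used for edge-band rendering).
scale_about_centroid <- function(poly, s) {
  ctr <- polygon_centroid(poly)
  poly <- as_polygon(poly)
  poly[, 1] <- ctr[1] + (poly[, 1] - ctr[1]) * s
  poly[, 2] <- ctr[2] + (poly[, 2] - ctr[2]) * s
  poly
}

#' Point-in-polygon test (even-odd rule)
#'
#' Crossing-number containment test with the half-open edge rule
#' `ymin <= y < ymax` and a strictly-left intersection comparison, so that
#' points on a left/top edge count as inside and points on a right/bottom
#' edge as outside. Vectorized over query points.
#'
#' @param px,py query point coordinates (0-based pixel coordinates).
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly)
  crossings <- integer(length(px))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xs[k2]; y2 <- ys[k2]
    if (y1 == y2) next
    hit <- (py >= pmin(y1, y2)) & (py < pmax(y1, y2))
    if (!any(hit)) next
    xint <- x1 + (py[hit] - y1) / (y2 - y1) * (x2 - x1)
    idx <- which(hit)
    crossings[idx] <- crossings[idx] + as.integer(px[idx] < xint)
  }
  crossings %% 2L == 1L
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel is foreground iff its center lies inside the polygon under the
#' even-odd rule (see [point_in_polygon()]). Self-intersecting polygons are
#' handled by the same rule. A degenerate (zero-area) polygon yields an
#' all-background mask with a warning.
#'
#' @param poly two-column vertex matrix, 0-based pixel coordinates.
#' @param shape integer vector `c(n_rows, n_cols)` of the target image.
#' @return logical matrix of dimension `shape`.
#' @export
rasterize_polygon <- function(poly, shape) {
  poly <- as_polygon(poly)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  mask <- matrix(FALSE, nr, nc)
  if (polygon_is_degenerate(poly)) {
    warn("degenerate zero-area polygon rasterized to an empty mask")
    return(mask)
  }
  xs <- poly[, 1]; ys <- poly[, 2]
  # bounding box of candidate pixels (1-based row/col); centers at idx - 0.5
  c1 <- max(1L, as.integer(floor(min(xs) + 0.5)) + 1L)
  c2 <- min(nc, as.integer(ceiling(max(xs) + 0.5)))
  r1 <- max(1L, as.integer(floor(min(ys) + 0.5)) + 1L)
  r2 <- min(nr, as.integer(ceiling(max(ys) + 0.5)))
  if (c1 > c2 || r1 > r2) return(mask)
  cx <- (c1:c2) - 0.5
  cy <- (r1:r2) - 0.5
  cross <- matrix(0L, length(cy), length(cx))
  n <- nrow(poly)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xs[k2]; y2 <- ys[k2]
    if (y1 == y2) next
    hit <- (cy >= pmin(y1, y2)) & (cy < pmax(y1, y2))
    if (!any(hit)) next
    xint <- x1 + (cy[hit] - y1) / (y2 - y1) * (x2 - x1)
    cross[hit, ] <- cross[hit, ] + outer(xint, cx, function(a, b) as.integer(b < a))
  }
  mask[r1:r2, c1:c2] <- cross %% 2L == 1L
  mask
}

# A polygon is degenerate when all vertices are collinear: the even-odd
# interior is empty. (The signed shoelace area is not usable here: it also
# vanishes for symmetric self-intersecting polygons, whose even-odd interior
# is non-empty.)
polygon_is_degenerate <- function(poly) {
  poly <- as_polygon(poly)
  v <- sweep(poly[-1, , drop = FALSE], 2, poly[1, ])
  if (nrow(v) < 2) return(TRUE)
  cross <- v[1, 1] * v[-1, 2] - v[1, 2] * v[-1, 1]
  all(abs(cross) < 1e-12)
}

# Simple-polygon check: any pair of non-adjacent edges intersecting?
# O(n^2); polygons here have < 100 vertices.
polygon_is_simple <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  seg <- function(k) {
    k2 <- if (k == n) 1L else k + 1L
    rbind(poly[k, ], poly[k2, ])
  }
  segs_intersect <- function(a, b) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    d1 <- d(b[1, ], b[2, ], a[1, ]); d2 <- d(b[1, ], b[2, ], a[2, ])
    d3 <- d(a[1, ], a[2, ], b[1, ]); d4 <- d(a[1, ], a[2, ], b[2, ])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through the wrap-around
      if (segs_intersect(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

# Parametric shape builders ---------------------------------------------------

# Rotated rectangle (rod-like crystal outline), centered at (cx, cy),
# `len` along the orientation axis, `wid` across it, angle in radians.
rect_polygon <- function(cx, cy, len, wid, theta) {
  u <- c(cos(theta), sin(theta)) * len / 2
  v <- c(-sin(theta), cos(theta)) * wid / 2
  rbind(
    c(cx, cy) + u + v,
    c(cx, cy) + u - v,
    c(cx, cy) - u - v,
    c(cx, cy) - u + v
  )
}

# Elongated hexagon (hexagonal-cross-section crystal outline).
hex_polygon <- function(cx, cy, len, wid, theta) {
  base <- rbind(
    c( 0.5,  0.0),
    c( 0.25, -0.5),
    c(-0.25, -0.5),
    c(-0.5,  0.0),
    c(-0.25,  0.5),
    c( 0.25,  0.5)
  )
  base[, 1] <- base[, 1] * len
  base[, 2] <- base[, 2] * wid
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  out <- base %*% t(rot)
  out[, 1] <- out[, 1] + cx
  out[, 2] <- out[, 2] + cy
  out
}

# Ellipse outline as a polygon (cell body), semi-axes a (along theta) and b.
ellipse_polygon <- function(cx, cy, a, b, theta, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(cx + x0 * cos(theta) - y0 * sin(theta),
        cy + x0 * sin(theta) + y0 * cos(theta))
}

#' Trace a binary mask to a polygon outline
#'
#' Follows the object contour (largest connected component) and pushes each
#' contour vertex half a pixel outward, away from the local foreground, so
#' that re-rasterizing the polygon recovers the mask including its boundary
#' pixels. Exact for convex blobs; small concavities may gain or lose a
#' boundary pixel.
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @return two-column vertex matrix (x, y), 0-based pixel coordinates.
#' @export
mask_to_polygon <- function(mask) {
  m <- mask != 0
  if (!any(m)) abort("cannot trace an empty mask to a polygon")
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  contours <- EBImage::ocontour(lab)
  sizes <- tabulate(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  ct <- contours[[which.max(sizes)]]  # 0-based (row, col) of boundary pixels
  nr <- nrow(m); nc <- ncol(m)
  verts <- matrix(0, nrow(ct), 2)
  for (i in seq_len(nrow(ct))) {
    r0 <- ct[i, 1]; c0 <- ct[i, 2]
    r <- r0 + 1L; c <- c0 + 1L
    up    <- r == 1L  || !m[r - 1L, c]
    down  <- r == nr  || !m[r + 1L, c]
    left  <- c == 1L  || !m[r, c - 1L]
    right <- c == nc  || !m[r, c + 1L]
    verts[i, ] <- c(c0 + 0.5 + 0.5 * (right - left),
                    r0 + 0.5 + 0.5 * (down - up))
  }
  verts[!duplicated(verts), , drop = FALSE]
}

# Tight 0-based bounding box of a mask: c(xmin, ymin, xmax, ymax), inclusive.
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("cannot compute the bounding box of an empty mask")
  c(xmin = min(idx[, 2]) - 1L, ymin = min(idx[, 1]) - 1L,
    xmax = max(idx[, 2]) - 1L, ymax = max(idx[, 1]) - 1L)
}

mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 0.5, y = mean(idx[, 1]) - 0.5)
}
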