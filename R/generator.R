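#' Configure the synthetic scene generator
#'
#' Builds the parametric description of one acquisition setup for synthetic
#' bright-field-like images of insect-cell cultures bearing intracellular
#' protein crystals. Two crystal morphologies are modelled:
#'
#' * class `G` — single large rod-like crystals, typically one per bearing
#'   cell, long axis up to 140 um, often protruding from the cell body;
#' * class `H` — smaller crystals with a hexagonal cross-section, growing
#'   inside the cell in random orientations with a marked tendency to
#'   cluster (several per bearing cell).
#'
#' The default (`"full"`) preset mirrors the acquisition geometry of the
#' real screening setup the generator emulates: 2136 x 2136 px frames
#' covering a 300 x 300 um field of view, downscaled to 512 x 512 PNG, with
#' a crystallization efficiency (fraction of cells bearing at least one
#' crystal) of 0.95 for class G and 0.85 for class H. The `"desk"` and
#' `"easy"` presets shrink the frame for fast CPU experiments; `"easy"`
#' additionally renders high-contrast crystals over faint cells, a
#' deliberately simple regime for training sanity checks.
#'
#' @param preset `"full"` (acquisition scale), `"desk"` or `"easy"`.
#' @param ... named overrides of individual fields, e.g.
#'   `generator_config("desk", efficiency_G = 0.5, crystal_classes = c("G", "H"))`.
#'   Recognised fields and defaults (full preset):
#'   `field_of_view_um` (300), `full_resolution_px` (2136),
#'   `output_resolution_px` (512), `cell_density` (range, c(10, 40)),
#'   `efficiency_G` (0.95), `efficiency_H` (0.85),
#'   `crystal_classes` ("G"; any subset of c("G","H") or "mixed" for both),
#'   `background_mean` (0.82), `background_sd` (0.025), `blur_sigma` (2),
#'   `cell_diameter_um` (c(15, 25)), `cell_contrast` (0.10),
#'   `rim_contrast` (0.12), `g_contrast` (+0.12: rod interiors render
#'   slightly bright, strongly refractile), `h_contrast` (-0.30: hexagonal
#'   crystals render dark), `edge_contrast` (0.30, dark edge band),
#'   `g_length_um` (c(20, 140)), `g_width_um` (c(3, 8)),
#'   `h_length_um` (c(3, 15)), `h_aspect` (0.6), `h_count_range` (c(1, 6)),
#'   `rng_seed` (1).
#' @return a `generator_config` object (validated list).
#' @export
generator_config <- function(preset = c("full", "desk", "easy"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    field_of_view_um = 300,
    full_resolution_px = 2136L,
    output_resolution_px = 512L,
    cell_density = c(10L, 40L),
    efficiency_G = 0.95,
    efficiency_H = 0.85,
    crystal_classes = "G",
    background_mean = 0.82,
    background_sd = 0.025,
    blur_sigma = 2,
    cell_diameter_um = c(15, 25),
    cell_contrast = 0.10,
    rim_contrast = 0.12,
    g_contrast = 0.12,
    h_contrast = -0.30,
    edge_contrast = 0.30,
    g_length_um = c(20, 140),
    g_width_um = c(3, 8),
    h_length_um = c(3, 15),
    h_aspect = 0.6,
    h_count_range = c(1L, 6L),
    rng_seed = 1L,
    preset = preset
  )
  overrides <- switch(preset,
    full = list(),
    desk = list(
      field_of_view_um = 75, full_resolution_px = 128L, output_resolution_px = 128L,
      cell_density = c(3L, 8L), cell_diameter_um = c(15, 25),
      g_length_um = c(15, 50), g_width_um = c(3, 7),
      h_length_um = c(4, 14), blur_sigma = 1
    ),
    easy = list(
      field_of_view_um = 60, full_resolution_px = 128L, output_resolution_px = 128L,
      cell_density = c(2L, 5L), cell_contrast = 0.03, rim_contrast = 0.03,
      g_contrast = -0.5, h_contrast = -0.5, edge_contrast = 0.3, background_sd = 0.015,
      g_length_um = c(10, 40), g_width_um = c(3, 7),
      h_length_um = c(4, 12), blur_sigma = 0.8
    )
  )
  cfg[names(overrides)] <- overrides
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop_field(unknown[1], "is not a generator parameter")
  }
  cfg[names(user)] <- user
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  chk_range01 <- function(field) {
    v <- cfg[[field]]
    if (!is_scalar_number(v) || v < 0 || v > 1) stop_field(field, "must be a number in [0, 1]")
  }
  chk_range01("efficiency_G")
  chk_range01("efficiency_H")
  if (!is_scalar_number(cfg$field_of_view_um) || cfg$field_of_view_um <= 0) {
    stop_field("field_of_view_um", "must be a positive number")
  }
  cfg$full_resolution_px <- as.integer(cfg$full_resolution_px)
  cfg$output_resolution_px <- as.integer(cfg$output_resolution_px)
  if (cfg$full_resolution_px < 16L) stop_field("full_resolution_px", "must be >= 16")
  if (cfg$full_resolution_px < cfg$output_resolution_px) {
    stop_field("output_resolution_px", "must not exceed full_resolution_px")
  }
  classes <- cfg$crystal_classes
  if ("mixed" %in% classes) classes <- union(setdiff(classes, "mixed"), c("G", "H"))
  if (length(classes) == 0L || !all(classes %in% c("G", "H"))) {
    stop_field("crystal_classes", "must be a subset of {G, H, mixed}")
  }
  cfg$crystal_classes <- sort(classes)
  for (field in c("cell_density", "cell_diameter_um", "g_length_um",
                  "g_width_um", "h_length_um", "h_count_range")) {
    v <- cfg[[field]]
    if (length(v) != 2L || !is.numeric(v) || any(v <= 0) || v[1] > v[2]) {
      stop_field(field, "must be an increasing positive range c(lo, hi)")
    }
  }
  for (field in c("g_contrast", "h_contrast")) {
    if (!is_scalar_number(cfg[[field]])) stop_field(field, "must be a signed number")
  }
  if (!is_scalar_number(cfg$background_sd) || cfg$background_sd < 0) {
    stop_field("background_sd", "must be a non-negative number")
  }
  if (!is_scalar_number(cfg$blur_sigma) || cfg$blur_sigma < 0) {
    stop_field("blur_sigma", "must be a non-negative number")
  }
  structure(cfg, class = "generator_config")
}

#' Physical pixel pitch of a generator configuration
#' @param config a [generator_config()].
#' @param at `"full"` (acquisition resolution) or `"output"` (after downscale).
#' @return micrometres per pixel.
#' @export
pixel_pitch <- function(config, at = c("full", "output")) {
  at <- match.arg(at)
  config$field_of_view_um /
    switch(at, full = config$full_resolution_px, output = config$output_resolution_px)
}

#' Sample a synthetic scene
#'
#' Draws one field of view: cell bodies are placed with rejection of pairs
#' overlapping by more than 60 percent, then each cell independently bears a
#' class-G crystal with probability `efficiency_G` and/or class-H crystals
#' with probability `efficiency_H` (for each enabled class). A bearing cell
#' holds exactly one G crystal; H crystal counts are sampled from
#' `h_count_range`, with two or more implying a cluster (shared `cluster_id`).
#' Deterministic for a fixed `(config, seed)` pair.
#'
#' @param config a [generator_config()].
#' @param seed integer seed for this scene.
#' @return a `crystal_scene`: list with the config, the seed, a `cells`
#'   tibble (center, semi-axes, orientation in full-resolution px) and a
#'   `crystals` tibble (class, host cell, polygon, physical size,
#'   orientation, cluster id).
#' @export
sample_scene <- function(config, seed) {
  config <- validate_generator_config(unclass(config))
  pitch <- pixel_pitch(config, "full")
  px <- config$full_resolution_px
  with_seed(seed, {
    n_cells <- sample(seq.int(config$cell_density[1], config$cell_density[2]), 1L)
    cells <- place_cells(n_cells, config, pitch, px)
    crystals <- list()
    next_cluster <- 1L
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      if ("G" %in% config$crystal_classes && runif(1) < config$efficiency_G) {
        crystals[[length(crystals) + 1L]] <- sample_g_crystal(cell, config, pitch)
      }
      if ("H" %in% config$crystal_classes && runif(1) < config$efficiency_H) {
        k <- sample(seq.int(config$h_count_range[1], config$h_count_range[2]), 1L)
        cl_id <- if (k >= 2L) next_cluster else NA_integer_
        if (k >= 2L) next_cluster <- next_cluster + 1L
        for (j in seq_len(k)) {
          crystals[[length(crystals) + 1L]] <- sample_h_crystal(cell, config, pitch, cl_id)
        }
      }
    }
    crystals <- if (length(crystals) > 0L) bind_rows(crystals) else tibble(
      crystal_class = character(), host_cell = integer(), polygon = list(),
      length_um = numeric(), width_um = numeric(), orientation = numeric(),
      cluster_id = integer()
    )
    structure(
      list(config = config, seed = as.integer(seed), cells = cells, crystals = crystals),
      class = "crystal_scene"
    )
  })
}

place_cells <- function(n_cells, config, pitch, px) {
  placed <- list()
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      d <- runif(2, config$cell_diameter_um[1], config$cell_diameter_um[2]) / pitch
      a <- max(d) / 2; b <- min(d) / 2
      cx <- runif(1, 0.05 * px, 0.95 * px)
      cy <- runif(1, 0.05 * px, 0.95 * px)
      r_new <- (a + b) / 2
      overlap_too_big <- FALSE
      for (p in placed) {
        r_old <- (p$a + p$b) / 2
        dist <- sqrt((cx - p$cx)^2 + (cy - p$cy)^2)
        frac <- circle_overlap_fraction(r_new, r_old, dist)
        if (frac > 0.6) { overlap_too_big <- TRUE; break }
      }
      if (!overlap_too_big) {
        placed[[length(placed) + 1L]] <- list(
          cell_id = i, cx = cx, cy = cy, a = a, b = b,
          orientation = runif(1, 0, pi), texture_seed = sample.int(2^30, 1)
        )
        ok <- TRUE
        break
      }
    }
    if (!ok) next  # frame too crowded; skip this cell
  }
  bind_rows(lapply(placed, as_tibble))
}

# Intersection area of two discs divided by the smaller disc's area.
circle_overlap_fraction <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(1)
  a1 <- r1^2 * acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  a3 <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
  (a1 + a2 - a3) / (pi * min(r1, r2)^2)
}

sample_g_crystal <- function(cell, config, pitch) {
  len_um <- min(runif(1, config$g_length_um[1], config$g_length_um[2]), 140)
  wid_um <- runif(1, config$g_width_um[1], config$g_width_um[2])
  theta <- runif(1, 0, pi)
  # anchored near the cell center; rods may protrude from the cell body
  cx <- cell$cx + runif(1, -0.3, 0.3) * cell$a
  cy <- cell$cy + runif(1, -0.3, 0.3) * cell$b
  tibble(
    crystal_class = "G", host_cell = cell$cell_id,
    polygon = list(rect_polygon(cx, cy, len_um / pitch, wid_um / pitch, theta)),
    length_um = len_um, width_um = wid_um, orientation = theta,
    cluster_id = NA_integer_
  )
}

sample_h_crystal <- function(cell, config, pitch, cluster_id) {
  len_um <- runif(1, config$h_length_um[1], config$h_length_um[2])
  wid_um <- len_um * config$h_aspect
  theta <- runif(1, 0, pi)  # random orientations
  # inside the host cell: position within 60% of the semi-axes, with
  # cluster members huddling around a common offset
  off_x <- runif(1, -0.5, 0.5); off_y <- runif(1, -0.5, 0.5)
  if (!is.na(cluster_id)) {
    off_x <- off_x * 0.35; off_y <- off_y * 0.35
    off_x <- off_x + rnorm(1, 0, 0.15); off_y <- off_y + rnorm(1, 0, 0.15)
  }
  off_x <- pmin(0.6, pmax(-0.6, off_x)); off_y <- pmin(0.6, pmax(-0.6, off_y))
  co <- cos(cell$orientation); si <- sin(cell$orientation)
  dx <- off_x * cell$a; dy <- off_y * cell$b
  cx <- cell$cx + dx * co - dy * si
  cy <- cell$cy + dx * si + dy * co
  tibble(
    crystal_class = "H", host_cell = cell$cell_id,
    polygon = list(hex_polygon(cx, cy, len_um / pitch, wid_um / pitch, theta)),
    length_um = len_um, width_um = wid_um, orientation = theta,
    cluster_id = cluster_id
  )
}

#' @export
print.crystal_scene <- function(x, ...) {
  cat(sprintf("<crystal_scene> seed %d: %d cells, %d crystals (%s)\n",
              x$seed, nrow(x$cells), nrow(x$crystals),
              paste(names(table(x$crystals$crystal_class)), collapse = "/")))
  invisible(x)
}
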