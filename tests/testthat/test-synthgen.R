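# Synthetic scene generator: determinism, efficiency recovery, geometry.

test_that("scene sampling is deterministic and honours zero efficiency", {
  cfg <- generator_config("desk", crystal_classes = c("G", "H"))
  s1 <- sample_scene(cfg, 42)
  s2 <- sample_scene(cfg, 42)
  expect_identical(s1, s2)
  s3 <- sample_scene(cfg, 43)
  expect_false(identical(s1$cells, s3$cells))

  cfg0 <- generator_config("desk", crystal_classes = "G", efficiency_G = 0)
  s0 <- sample_scene(cfg0, 7)
  expect_equal(nrow(s0$crystals), 0)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generator_config("desk", efficiency_G = 1.2), "efficiency_G")
  expect_error(generator_config("desk", output_resolution_px = 4096), "output_resolution_px")
  expect_error(generator_config("desk", crystal_classes = "X"), "crystal_classes")
  expect_error(generator_config("desk", nonsense = 1), "nonsense")
})

test_that("observed crystallization efficiency recovers the configured rate (3 binomial sigma)", {
  cfg <- generator_config("desk", crystal_classes = c("G", "H"),
                          cell_density = c(25L, 35L))
  n_cells <- 0; n_g_bearing <- 0; n_h_bearing <- 0
  i <- 0
  while (n_cells < 1000) {
    i <- i + 1
    sc <- sample_scene(cfg, i)
    n_cells <- n_cells + nrow(sc$cells)
    g_cells <- unique(sc$crystals$host_cell[sc$crystals$crystal_class == "G"])
    h_cells <- unique(sc$crystals$host_cell[sc$crystals$crystal_class == "H"])
    n_g_bearing <- n_g_bearing + length(g_cells)
    n_h_bearing <- n_h_bearing + length(h_cells)
  }
  sigma_g <- sqrt(0.95 * 0.05 / n_cells)
  sigma_h <- sqrt(0.85 * 0.15 / n_cells)
  expect_lt(abs(n_g_bearing / n_cells - 0.95), 3 * sigma_g)
  expect_lt(abs(n_h_bearing / n_cells - 0.85), 3 * sigma_h)
})

test_that("scene invariants hold: one G per cell, H inside host, clusters shared", {
  cfg <- generator_config("desk", crystal_classes = c("G", "H"))
  for (seed in 1:10) {
    sc <- sample_scene(cfg, seed)
    g <- sc$crystals[sc$crystals$crystal_class == "G", ]
    expect_true(all(table(g$host_cell) <= 1))
    expect_true(all(g$length_um <= 140))
    h <- sc$crystals[sc$crystals$crystal_class == "H", ]
    if (nrow(h) > 0) {
      # H centers fall inside the host-cell ellipse
      for (k in seq_len(nrow(h))) {
        cell <- sc$cells[sc$cells$cell_id == h$host_cell[k], ]
        ctr <- colMeans(h$polygon[[k]])
        co <- cos(cell$orientation); si <- sin(cell$orientation)
        dx <- ctr[1] - cell$cx; dy <- ctr[2] - cell$cy
        u <- (dx * co + dy * si) / cell$a
        v <- (-dx * si + dy * co) / cell$b
        expect_lte(u^2 + v^2, 1)
      }
      # multi-crystal cells share one cluster id; single crystals have none
      per_cell <- split(h$cluster_id, h$host_cell)
      for (ids in per_cell) {
        if (length(ids) >= 2) expect_equal(length(unique(ids)), 1)
        else expect_true(is.na(ids))
      }
    }
  }
})

test_that("rendered full-resolution geometry matches the physical constants", {
  cfg <- generator_config("full")
  expect_equal(pixel_pitch(cfg, "full"), 300 / 2136)
  # a 140 um rod spans ~997 px at acquisition resolution
  pitch <- pixel_pitch(cfg, "full")
  rod <- cellcryst:::rect_polygon(1068, 1068, 140 / pitch, 5 / pitch, 0)
  mask <- rasterize_polygon(rod, c(2136, 2136))
  extent <- diff(range(which(colSums(mask) > 0))) + 1
  expect_equal(extent, 997, tolerance = 2 / 997)
})

test_that("rendering yields one instance per object with non-empty masks", {
  cfg <- generator_config("desk", crystal_classes = "G", cell_density = c(1L, 1L),
                          efficiency_G = 1)
  sc <- sample_scene(cfg, 5)
  ann <- render_scene(sc)
  expect_s3_class(ann, "annotated_image")
  expect_equal(sum(ann$instances$label == "crystal_G"), nrow(sc$crystals))
  expect_equal(sum(ann$instances$label == "cell"), nrow(sc$cells))
  masks <- instance_masks(ann, labels = "^crystal")
  expect_true(all(vapply(masks, sum, numeric(1)) >= 1))
  expect_equal(dim(ann$image), c(128, 128))
  expect_true(all(ann$image >= 0 & ann$image <= 1))
  # rendering is deterministic given the scene
  expect_identical(render_scene(sc)$image, ann$image)
})

test_that("generate_dataset writes a reproducible dataset with a readable manifest", {
  cfg <- generator_config("desk", crystal_classes = c("G", "H"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, 3, seed = 9, out_dir = d1)
  m2 <- generate_dataset(cfg, 3, seed = 9, out_dir = d2)
  expect_equal(nrow(m1), 3)
  for (f in m1$annotation_path) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(
    readBin(file.path(d1, m1$image_path[1]), "raw", 1e6),
    readBin(file.path(d2, m2$image_path[1]), "raw", 1e6)
  )
  back <- read_manifest(file.path(d1, "manifest.tsv"))
  expect_equal(nrow(back), 3)
  expect_equal(attr(back, "seed"), 9L)
  expect_error(generate_dataset(cfg, 0, seed = 1, out_dir = d1), "n_images")
  # growing the dataset does not change earlier images
  d3 <- withr::local_tempdir()
  m3 <- generate_dataset(cfg, 4, seed = 9, out_dir = d3)
  expect_identical(readLines(file.path(d1, m1$annotation_path[2])),
                   readLines(file.path(d3, m3$annotation_path[2])))
})
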