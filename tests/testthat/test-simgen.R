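# Synthetic scene generation and rendering.

test_that("requested class counts are realized exactly and scenes are deterministic", {
  pr <- small_prior(seed = 5, class_counts = c(dot = 10, rod = 5, network = 2),
                    cell_radius_um = 7)
  sc <- generate_scene(pr)
  counts <- table(factor(sc$components$true_class,
                         levels = c("dot", "rod", "network")))
  expect_equal(as.integer(counts), c(10L, 5L, 2L))

  sc2 <- generate_scene(small_prior(seed = 5,
                                    class_counts = c(dot = 10, rod = 5,
                                                     network = 2),
                                    cell_radius_um = 7))
  expect_identical(sc$components$true_total_length_um,
                   sc2$components$true_total_length_um)
  expect_identical(sc$puncta, sc2$puncta)
  expect_identical(sc$cell_labels, sc2$cell_labels)
})

test_that("ground-truth classes always satisfy the classification rule", {
  n_checked <- 0L
  for (s in 1:12) {
    sc <- small_scene(s)
    cls <- as.character(classify_component(sc$components$true_total_length_um,
                                           sc$components$true_n_junctions))
    expect_identical(cls, sc$components$true_class)
    n_checked <- n_checked + nrow(sc$components)
  }
  expect_gte(n_checked, 80L)
})

test_that("scene invariants hold: puncta in image, valid cell references, nucleus spacing", {
  for (s in c(3, 9)) {
    sc <- small_scene(s, n_cells = 2L, cell_radius_um = 5,
                      image_shape = c(512L, 512L))
    W <- sc$image_shape[2L] * sc$pixel_size_um
    H <- sc$image_shape[1L] * sc$pixel_size_um
    expect_true(all(sc$puncta$x_um > 0 & sc$puncta$x_um < W))
    expect_true(all(sc$puncta$y_um > 0 & sc$puncta$y_um < H))
    expect_true(all(sc$puncta$cell_id %in% sc$cells$cell_id))
    if (nrow(sc$cells) > 1L) {
      d <- as.matrix(dist(sc$cells[, c("nucleus_x_um", "nucleus_y_um")]))
      diag(d) <- Inf
      expect_gte(min(d), 2 * sc$cells$nucleus_radius_um[1L])
    }
  }
})

test_that("infeasible geometry raises a placement error instead of truncating", {
  pr <- scene_prior(image_shape = c(64L, 64L), n_cells = 5L,
                    cell_radius_um = 6, seed = 1)
  expect_error(generate_scene(pr), class = "mitoquant_placement_error")
})

test_that("zero-signal render is exactly the background level", {
  sc <- small_scene(3)
  img <- render_image(sc, optics_params(photons_per_unit = 0,
                                        read_noise_sd = 0, background = 11),
                      seed = 1)
  expect_true(all(img$data == 11))
})

test_that("identity optics reproduce the rasterized structure support", {
  sc <- small_scene(3)
  img <- render_image(sc, ideal_optics())
  expect_identical(get_channel(img, "EGFP") > 0, rasterize_scene(sc, "mito"))
  expect_identical(get_channel(img, "DAPI") > 0,
                   rasterize_scene(sc, "nuclei"))
  # red-only puncta contribute to mCherry but never to EGFP
  ro_mask <- rasterize_scene(sc, "red_only")
  expect_true(all(get_channel(img, "mCherry")[ro_mask] > 0))
  expect_true(all(get_channel(img, "EGFP")[ro_mask & !rasterize_scene(sc, "mito")] == 0))
})

test_that("noise-free intensity scales linearly with photons_per_unit", {
  sc <- small_scene(3)
  i1 <- render_image(sc, ideal_optics(photons_per_unit = 50))
  i2 <- render_image(sc, ideal_optics(photons_per_unit = 100))
  expect_lt(max(abs(i2$data - 2 * i1$data)), 1e-9 * max(i2$data))
})

test_that("PSF convolution conserves total intensity to within 0.1%", {
  sc <- small_scene(3)
  st <- mitoquant:::render_channel_structure(sc, "EGFP")
  for (fwhm in c(0.25, 0.6)) {
    bl <- mitoquant:::blur_gaussian(
      st, mitoquant:::fwhm_to_sigma_px(fwhm, sc$pixel_size_um))
    expect_lt(abs(sum(bl) - sum(st)) / sum(st), 1e-3)
  }
})

test_that("rendered red-only puncta have mCherry above 1.5x EGFP at default optics", {
  n_ok <- 0L
  n_tot <- 0L
  for (s in 1:4) {
    sc <- small_scene(s, prob_red_only_cell = 1,
                      n_red_only_per_cell_dist = c(mean = 6))
    img <- render_image(sc, optics_params(), seed = 40 + s)
    e <- get_channel(img, "EGFP")
    m <- get_channel(img, "mCherry")
    px <- round(mitoquant:::um_to_px(sc$puncta$x_um, sc$puncta$y_um,
                                     sc$pixel_size_um))
    n_ok <- n_ok + sum(m[px] > 1.5 * e[px])
    n_tot <- n_tot + nrow(sc$puncta)
  }
  expect_gte(n_tot, 20L)
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("identical seeds give bit-identical rendered images", {
  sc <- small_scene(3)
  i1 <- render_image(sc, optics_params(), seed = 77)
  i2 <- render_image(sc, optics_params(), seed = 77)
  expect_identical(i1$data, i2$data)
})

test_that("undersampled PSF warns rather than errors", {
  sc <- small_scene(3)
  expect_warning(render_image(sc, optics_params(psf_fwhm_um = 0.01),
                              seed = 1),
                 "undersampled")
})

test_that("z-stack rendering and max projection have consistent shapes", {
  sc <- small_scene(3)
  iz <- render_image(sc, optics_params(), seed = 5, n_slices = 3L)
  expect_length(dim(iz$data), 4L)
  pr <- max_project(iz)
  expect_identical(dim(pr$data), dim(iz$data)[1:3])
  expect_true(all(pr$data == apply(iz$data, c(1, 2, 3), max)))
})

test_that("scene truth writes and reads back exactly", {
  sc <- small_scene(3)
  dir <- withr::local_tempdir()
  write_scene_truth(sc, dir)
  tt <- read_scene_truth(dir)
  expect_equal(nrow(tt$components), nrow(sc$components))
  expect_identical(tt$components$true_class, sc$components$true_class)
  expect_equal(tt$components$true_total_length_um,
               sc$components$true_total_length_um)
  expect_equal(nrow(tt$puncta), nrow(sc$puncta))
  expect_identical(as.integer(tt$cell_labels), as.integer(sc$cell_labels))
  expect_identical(tt$mito_mask > 0, rasterize_scene(sc, "mito"))
})

test_that("an empty scene writes headers-only tables and blank masks", {
  sc <- generate_scene(scene_prior(image_shape = c(64L, 64L), n_cells = 0L,
                                   seed = 1))
  dir <- withr::local_tempdir()
  write_scene_truth(sc, dir)
  tt <- read_scene_truth(dir)
  expect_equal(nrow(tt$components), 0L)
  expect_equal(nrow(tt$puncta), 0L)
  expect_true(all(tt$cell_labels == 0))
  expect_true(all(tt$mito_mask == 0))
})

test_that("multichannel TIFF round-trips counts and metadata", {
  sc <- small_scene(3)
  img <- render_image(sc, optics_params(), seed = 3)
  f <- withr::local_tempfile(fileext = ".tif")
  write_multichannel_tiff(img, f)
  rt <- read_multichannel_tiff(f)
  expect_identical(rt$channel_names, img$channel_names)
  expect_equal(rt$pixel_size_um, img$pixel_size_um)
  expect_lte(max(abs(rt$data - img$data)), 1) # 16-bit integer quantization
})
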