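# Red-only channel arithmetic, spot detection and per-cell quantification.

test_that("the red-only rule matches a brute-force per-pixel evaluation", {
  set.seed(11)
  egfp <- matrix(runif(40 * 50, 0, 200), 40, 50)
  mch <- matrix(runif(40 * 50, 0, 320), 40, 50)
  pp <- puncta_params(min_intensity = 25)
  got <- red_only_channel(egfp, mch, pp)
  want <- matrix(0, 40, 50)
  for (r in 1:40) {
    for (c in 1:50) {
      if (mch[r, c] > 1.5 * egfp[r, c] && mch[r, c] >= 25) {
        want[r, c] <- mch[r, c]
      }
    }
  }
  expect_identical(got, want)
})

test_that("the 1.5x boundary is strict and the floor zeroes dim pixels", {
  e <- matrix(c(100, 100, 0), 1, 3)
  m <- matrix(c(151, 150, 10), 1, 3)
  out <- red_only_channel(e, m, puncta_params(min_intensity = 20))
  expect_equal(as.vector(out), c(151, 0, 0))
  expect_error(red_only_channel(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("red_only_channel is idempotent and monotone in the factor", {
  sc <- small_scene(3, prob_red_only_cell = 1)
  img <- render_image(sc, optics_params(), seed = 21)
  e <- get_channel(img, "EGFP")
  m <- get_channel(img, "mCherry")
  pp <- puncta_params(min_intensity = 30)
  ro <- red_only_channel(e, m, pp)
  # idempotent: re-applying the rule to its own output changes nothing
  expect_identical(red_only_channel(e, ro, pp) > 0, ro > 0)
  prev <- ro > 0
  for (f in c(2, 3, 5)) {
    cur <- red_only_channel(e, m, puncta_params(redonly_factor = f,
                                                min_intensity = 30)) > 0
    expect_true(all(!cur | prev)) # raising the factor never adds pixels
    prev <- cur
  }
})

test_that("detection resolves well-separated synthetic blobs and empty input", {
  ps <- 0.05
  ch <- matrix(0, 128, 128)
  # two Gaussian blobs 1.5 um apart (3x the 0.5 um spot diameter)
  for (ctr in list(c(40, 40), c(40, 70))) {
    for (r in 1:128) {
      for (c in 1:128) {
        d2 <- (r - ctr[1])^2 + (c - ctr[2])^2
        ch[r, c] <- ch[r, c] + 500 * exp(-d2 / (2 * 2.5^2))
      }
    }
  }
  sp <- detect_spots(ch, ps, puncta_params())
  expect_equal(nrow(sp), 2L)
  expect_equal(sort(sp$y_um), c(39.5, 39.5) * ps + 0 * ps, tolerance = 0.1)

  expect_equal(nrow(detect_spots(matrix(0, 64, 64), ps, puncta_params())),
               0L)
})

test_that("rendered puncta are detected with >= 0.9 recall and precision", {
  tp <- 0L
  n_det <- 0L
  n_truth <- 0L
  for (s in 1:6) {
    sc <- small_scene(s, prob_red_only_cell = 1,
                      n_red_only_per_cell_dist = c(mean = 8),
                      n_components_per_cell = 6)
    img <- render_image(sc, optics_params(), seed = 200 + s)
    q <- quantify_mitophagy(img)
    sp <- q$spots[!q$spots$edge_excluded, , drop = FALSE]
    tr <- truth_retained(sc)
    tp <- tp + match_spots(sp, tr, tol_um = 0.25)
    n_det <- n_det + nrow(sp)
    n_truth <- n_truth + nrow(tr)
    # edge-rule invariant on every frame
    W <- sc$image_shape[2L] * sc$pixel_size_um
    H <- sc$image_shape[1L] * sc$pixel_size_um
    d <- pmin(sp$x_um, W - sp$x_um, sp$y_um, H - sp$y_um)
    expect_true(all(d >= 1))
  }
  expect_gte(n_truth, 40L)
  expect_gte(tp / n_truth, 0.9)
  expect_gte(tp / n_det, 0.9)
})

test_that("edge exclusion flags exactly the spots inside the margin", {
  sp <- tibble::tibble(
    spot_id = 1:3, x_um = c(0.5, 1.5, 12), y_um = c(6, 6, 6),
    diameter_um = 0.5, response = 1, intensity_mean = 1,
    edge_excluded = FALSE, cell_id = NA_integer_, lyso_positive = NA
  )
  shape <- c(256L, 256L) # 12.8 x 12.8 um at 0.05
  out <- exclude_edge_spots(sp, shape, 0.05, puncta_params())
  expect_equal(out$edge_excluded, c(TRUE, FALSE, TRUE))
  out0 <- exclude_edge_spots(sp, shape, 0.05,
                             puncta_params(edge_margin_um = 0))
  expect_false(any(out0$edge_excluded))
})

test_that("nuclei are counted correctly, including touching pairs and blanks", {
  sc <- small_scene(8, n_cells = 2L, cell_radius_um = 5,
                    image_shape = c(512L, 512L))
  img <- render_image(sc, optics_params(), seed = 31)
  nuc <- detect_nuclei(get_channel(img, "DAPI"), img$pixel_size_um)
  expect_equal(nrow(nuc$nuclei), nrow(sc$cells))

  # two truly touching discs split by the watershed
  dapi <- matrix(0, 200, 200)
  for (ctr in list(c(100, 80), c(100, 121))) {
    idx <- mitoquant:::rasterize_disc((ctr[2] - 0.5) * 0.05,
                                      (ctr[1] - 0.5) * 0.05, 1.1, 0.05,
                                      c(200L, 200L))
    dapi[idx] <- 300
  }
  nuc2 <- detect_nuclei(dapi, 0.05)
  expect_equal(nrow(nuc2$nuclei), 2L)

  blank <- detect_nuclei(matrix(10, 64, 64), 0.05)
  expect_equal(nrow(blank$nuclei), 0L)
  q <- quantify_frame(tibble::tibble()[0, ], n_cells = 0L)
  expect_false(q$valid)
})

test_that("spots are assigned to containing masks, else nearest nucleus with low-id ties", {
  nuclei <- tibble::tibble(cell_id = 1:2, x_um = c(2, 8), y_um = c(5, 5),
                           area_um2 = 20)
  sp <- tibble::tibble(
    spot_id = 1:2, x_um = c(5, 3), y_um = c(5, 5), diameter_um = 0.5,
    response = 1, intensity_mean = 1, edge_excluded = FALSE,
    cell_id = NA_integer_, lyso_positive = NA
  )
  out <- assign_spots_to_cells(sp, nuclei)
  expect_equal(out$cell_id, c(1L, 1L)) # equidistant -> lowest cell_id

  labels <- matrix(0L, 200, 200)
  labels[, 101:200] <- 2L
  labels[, 1:100] <- 1L
  out2 <- assign_spots_to_cells(sp, nuclei, cell_labels = labels,
                                pixel_size_um = 0.05)
  expect_equal(out2$cell_id, c(1L, 1L))
  sp$x_um <- c(6, 3) # x = 6 um -> column 120 -> mask 2
  out3 <- assign_spots_to_cells(sp, nuclei, cell_labels = labels,
                                pixel_size_um = 0.05)
  expect_equal(out3$cell_id, c(2L, 1L))

  expect_true(all(is.na(
    assign_spots_to_cells(sp, nuclei[0, , drop = FALSE])$cell_id)))
})

test_that("ground-truth cell assignment is recovered on rendered frames", {
  sc <- small_scene(9, n_cells = 2L, cell_radius_um = 5,
                    image_shape = c(512L, 512L), prob_red_only_cell = 1,
                    n_red_only_per_cell_dist = c(mean = 5))
  img <- render_image(sc, optics_params(), seed = 77)
  q <- quantify_mitophagy(img)
  sp <- q$spots[!q$spots$edge_excluded, , drop = FALSE]
  tr <- truth_retained(sc)
  n_match <- 0L
  n_tot <- 0L
  for (i in seq_len(nrow(sp))) {
    d <- sqrt((tr$x_um - sp$x_um[i])^2 + (tr$y_um - sp$y_um[i])^2)
    j <- which.min(d)
    if (d[j] <= 0.25) {
      n_tot <- n_tot + 1L
      # detected nuclei ids may be permuted; compare via nearest truth nucleus
      nd <- sqrt((sc$cells$nucleus_x_um - q$nuclei$x_um[sp$cell_id[i]])^2 +
                   (sc$cells$nucleus_y_um - q$nuclei$y_um[sp$cell_id[i]])^2)
      if (sc$cells$cell_id[which.min(nd)] == tr$cell_id[j]) {
        n_match <- n_match + 1L
      }
    }
  }
  expect_gte(n_tot, 5L)
  expect_gte(n_match / n_tot, 0.9)
})

test_that("frame quantification arithmetic matches hand counts", {
  mk_spots <- function(cells) tibble::tibble(
    spot_id = seq_along(cells), x_um = 5, y_um = 5, diameter_um = 0.5,
    response = 1, intensity_mean = 1, edge_excluded = FALSE,
    cell_id = cells, lyso_positive = NA
  )
  q <- quantify_frame(mk_spots(c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4, 4, 5, 5, 5, 5)),
                      n_cells = 10L)
  expect_equal(q$pct_cells_with_red_only, 50)
  expect_equal(q$dots_per_positive_cell, 3)
  expect_equal(q$dots_per_total_cells, 1.5)

  q0 <- quantify_frame(mk_spots(integer(0)), n_cells = 8L)
  expect_equal(q0$pct_cells_with_red_only, 0)
  expect_true(is.na(q0$dots_per_positive_cell))
  expect_equal(q0$dots_per_total_cells, 0)

  q1 <- quantify_frame(mk_spots(c(1, 1, 1, 1)), n_cells = 1L)
  expect_equal(q1$pct_cells_with_red_only, 100)
  expect_equal(q1$dots_per_positive_cell, 4)
  expect_equal(q1$dots_per_total_cells, 4)

  # counting consistency: per-cell counts sum to the total
  sp <- mk_spots(c(1, 1, 2, 3, 3, 3))
  q2 <- quantify_frame(sp, n_cells = 4L)
  expect_equal(sum(table(sp$cell_id)), q2$n_spots)
})

test_that("lysosome colocalization recovers forced and intermediate rates", {
  for (prob in c(1, 0)) {
    sc <- small_scene(20 + prob, prob_red_only_cell = 1,
                      n_red_only_per_cell_dist = c(mean = 5),
                      lyso_colocalization_prob = prob)
    img <- render_image(sc, optics_params(), seed = 300 + prob)
    q <- quantify_mitophagy(img)
    expect_equal(q$frame$lyso_fraction, prob, tolerance = 1e-9)
  }
  # intermediate rate: binomial agreement over pooled puncta
  flags <- integer(0)
  for (s in 31:36) {
    sc <- small_scene(s, prob_red_only_cell = 1,
                      n_red_only_per_cell_dist = c(mean = 8),
                      n_components_per_cell = 6,
                      lyso_colocalization_prob = 0.7)
    img <- render_image(sc, optics_params(), seed = 400 + s)
    q <- quantify_mitophagy(img)
    flags <- c(flags, q$spots$lyso_positive[!q$spots$edge_excluded])
  }
  expect_gte(length(flags), 40L)  # pooled puncta across frames
  expect_lt(abs(mean(flags) - 0.7), 0.15)
})

test_that("line profiles interpolate constants and resolve red-only peaks", {
  flat <- multichannel_image(array(42, dim = c(64L, 64L, 1L)), "EGFP", 0.05)
  lp <- line_profile(flat, c(0.5, 0.5), c(2.5, 2.5), 21L)
  expect_true(all(lp$intensity == 42))
  lp1 <- line_profile(flat, c(1, 1), c(1, 1), 5L)
  expect_equal(nrow(lp1), 5L)
  expect_true(all(lp1$distance_um == 0))
  expect_error(line_profile(flat, c(-1, 0), c(1, 1)), "inside")

  sc <- small_scene(3, prob_red_only_cell = 1)
  img <- render_image(sc, optics_params(), seed = 5)
  p <- sc$puncta[1, ]
  lp2 <- line_profile(img, c(p$x_um - 1, p$y_um), c(p$x_um + 1, p$y_um),
                      81L)
  mch <- lp2[lp2$channel == "mCherry", ]
  egf <- lp2[lp2$channel == "EGFP", ]
  i <- which.max(mch$intensity)
  expect_gt(mch$intensity[i], 1.5 * egf$intensity[i])
})

test_that("the same spot machinery quantifies PLA puncta per cell", {
  sc <- small_scene(12, n_pla_per_cell_dist = c(mean = 6),
                    n_components_per_cell = 4, prob_red_only_cell = 0)
  img <- render_image(sc, optics_params(), seed = 50)
  expect_true("PLA" %in% img$channel_names)
  q <- quantify_pla(img)
  W <- sc$image_shape[2L] * sc$pixel_size_um
  tr <- sc$pla
  d <- pmin(tr$x_um, W - tr$x_um, tr$y_um, W - tr$y_um)
  n_expect <- sum(d >= 1) / nrow(sc$cells)
  expect_equal(q$n_pla_puncta_per_cell, n_expect, tolerance = 0.35)
  expect_true(q$valid)
})
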