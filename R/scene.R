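# Synthetic scene generation: ground-truthed cell layouts, mitochondrial
# geometries (dots / rods / networks), red-only puncta and PLA puncta.

in_ellipse <- function(x, y, cx, cy, a, b, theta) {
  ct <- cos(theta)
  st <- sin(theta)
  u <- ct * (x - cx) + st * (y - cy)
  v <- -st * (x - cx) + ct * (y - cy)
  u^2 / a^2 + v^2 / b^2 <= 1
}

ellipse_pixels <- function(shape, pixel_size_um, cx, cy, a, b, theta) {
  ps <- pixel_size_um
  rmax <- max(a, b)
  r0 <- max(1L, floor((cy - rmax) / ps))
  r1 <- min(shape[1L], ceiling((cy + rmax) / ps) + 1L)
  c0 <- max(1L, floor((cx - rmax) / ps))
  c1 <- min(shape[2L], ceiling((cx + rmax) / ps) + 1L)
  rows <- r0:r1
  cols <- c0:c1
  y <- (rep(rows, times = length(cols)) - 0.5) * ps
  x <- (rep(cols, each = length(rows)) - 0.5) * ps
  keep <- in_ellipse(x, y, cx, cy, a, b, theta)
  rr <- rep(rows, times = length(cols))[keep]
  cc <- rep(cols, each = length(rows))[keep]
  (cc - 1L) * shape[1L] + rr
}

sample_point_in_ellipse <- function(cx, cy, a, b, theta, shrink, max_tries = 200L) {
  ae <- a - shrink
  be <- b - shrink
  if (ae <= 0 || be <= 0) {
    return(NULL)
  }
  for (i in seq_len(max_tries)) {
    x <- cx + runif(1, -ae, ae)
    y <- cy + runif(1, -be, be)
    if (in_ellipse(x, y, cx, cy, ae, be, theta)) {
      return(c(x, y))
    }
  }
  NULL
}

# Arc polyline of arc length `len_um` starting at origin with heading `angle`,
# turning by a total angle `turn` (0 = straight). Points every `step_um`.
arc_polyline <- function(len_um, angle, turn, step_um = 0.05) {
  n <- max(2L, ceiling(len_um / step_um) + 1L)
  s <- seq(0, len_um, length.out = n)
  if (abs(turn) < 1e-6) {
    x <- s * cos(angle)
    y <- s * sin(angle)
  } else {
    r <- len_um / turn
    phi <- s / r
    # circle through origin, tangent to `angle` at s = 0
    x0 <- r * sin(phi)
    y0 <- r * (1 - cos(phi))
    x <- x0 * cos(angle) - y0 * sin(angle)
    y <- x0 * sin(angle) + y0 * cos(angle)
  }
  cbind(x, y)
}

rtrunc_norm <- function(mean, sd, lower) {
  for (i in 1:200) {
    v <- rnorm(1, mean, sd)
    if (v >= lower) {
      return(v)
    }
  }
  lower
}

# Component geometries in local coordinates (origin at anchor point).
# Each returns list(polylines, n_tips, n_junctions).
sample_dot_geom <- function(prior) {
  len <- max(prior$dot_diameter_um - prior$tubule_width_um,
             prior$pixel_size_um)
  ang <- runif(1, 0, pi)
  list(polylines = list(arc_polyline(len, ang, 0)), n_tips = 2L,
       n_junctions = 0L)
}

sample_rod_geom <- function(prior) {
  len <- rtrunc_norm(prior$rod_length_dist[["mean"]],
                     prior$rod_length_dist[["sd"]], prior$rod_min_length_um)
  poly_len <- len - prior$tubule_width_um
  ang <- runif(1, 0, 2 * pi)
  turn <- runif(1, 0.05, 0.5) * sample(c(-1, 1), 1)
  list(polylines = list(arc_polyline(poly_len, ang, turn)), n_tips = 2L,
       n_junctions = 0L)
}

sample_network_geom <- function(prior) {
  kr <- prior$network_branch_count_dist
  k <- if (kr[[1L]] >= kr[[2L]]) kr[[1L]] else sample(kr[[1L]]:kr[[2L]], 1L)
  # branch directions with a minimum angular gap, so neighbouring branches
  # separate within a fraction of their length at the rendered tubule width
  # (otherwise the junction is unresolvable by construction)
  min_gap <- min(0.9, 2 * pi / k * 0.8)
  gaps <- runif(k)
  gaps <- gaps / sum(gaps) * (2 * pi - k * min_gap)
  angles <- runif(1, 0, 2 * pi) + cumsum(min_gap + gaps)
  bl <- prior$network_branch_length_dist
  polylines <- vector("list", k)
  # the 0.7 um floor keeps every branch resolvable after tip erosion and
  # junction merging at the rendered tubule width
  for (i in seq_len(k)) {
    len <- rtrunc_norm(bl[["mean"]], bl[["sd"]], 0.7)
    turn <- runif(1, 0.02, 0.3) * sample(c(-1, 1), 1)
    polylines[[i]] <- arc_polyline(len, angles[i], turn)
  }
  n_tips <- k
  n_junctions <- 1L
  if (k >= 3L && runif(1) < 0.3) {
    # secondary junction: two sub-branches sprouting from branch 1's tip
    tip_poly <- polylines[[1L]]
    tip <- tip_poly[nrow(tip_poly), ]
    d <- tip_poly[nrow(tip_poly), ] - tip_poly[nrow(tip_poly) - 1L, ]
    tip_ang <- atan2(d[2L], d[1L])
    for (sgn in c(-1, 1)) {
      len <- rtrunc_norm(bl[["mean"]] * 0.8, bl[["sd"]] * 0.7, 0.6)
      sub <- arc_polyline(len, tip_ang + sgn * runif(1, 0.6, 1.0),
                          runif(1, 0.02, 0.2) * sample(c(-1, 1), 1))
      polylines <- c(polylines, list(sweep(sub, 2L, -tip)))
    }
    n_tips <- k + 1L
    n_junctions <- 2L
  }
  list(polylines = polylines, n_tips = n_tips, n_junctions = n_junctions)
}

translate_polys <- function(polylines, center) {
  lapply(polylines, function(p) sweep(p, 2L, -center))
}

placement_error <- function(what) {
  abort(
    sprintf(paste0(
      "could not place %s within the scene geometry; ",
      "enlarge image_shape, reduce counts or sizes"), what),
    class = "mitoquant_placement_error"
  )
}

place_cells <- function(prior) {
  shape <- prior$image_shape
  ps <- prior$pixel_size_um
  W <- shape[2L] * ps
  H <- shape[1L] * ps
  n <- prior$n_cells
  margin <- 0.3
  nuc_min_dist <- 4 * prior$nucleus_radius_um # edge gap >= one diameter
  cells <- list()
  cell_labels <- matrix(0L, shape[1L], shape[2L])
  add_cell <- function(i, cx, cy, a, b, theta) {
    pix <- ellipse_pixels(shape, ps, cx, cy, a, b, theta)
    if (any(cell_labels[pix] > 0L)) {
      return(FALSE)
    }
    jit <- min(a, b) - prior$nucleus_radius_um - 0.3
    nx_ <- cx + runif(1, -1, 1) * max(0, 0.15 * jit)
    ny_ <- cy + runif(1, -1, 1) * max(0, 0.15 * jit)
    for (cc in cells) {
      if (sqrt((nx_ - cc$nucleus_x_um)^2 + (ny_ - cc$nucleus_y_um)^2) <
          nuc_min_dist) {
        return(FALSE)
      }
    }
    cell_labels[pix] <<- i
    cells[[i]] <<- list(
      cell_id = i, center_x_um = cx, center_y_um = cy, axis_a_um = a,
      axis_b_um = b, theta = theta, nucleus_x_um = nx_, nucleus_y_um = ny_,
      nucleus_radius_um = prior$nucleus_radius_um
    )
    TRUE
  }
  if (n == 0L) {
    return(list(cells = tibble(
      cell_id = integer(), center_x_um = double(), center_y_um = double(),
      axis_a_um = double(), axis_b_um = double(), theta = double(),
      nucleus_x_um = double(), nucleus_y_um = double(),
      nucleus_radius_um = double()
    ), cell_labels = cell_labels))
  }
  if (prior$layout == "grid") {
    g <- ceiling(sqrt(n))
    sx <- W / g
    sy <- H / ceiling(n / g)
    amax <- prior$cell_radius_um * 1.15
    if (amax + margin > min(sx, sy) / 2) {
      placement_error(sprintf("%d cells on a grid", n))
    }
    i <- 0L
    for (gy in seq_len(ceiling(n / g))) {
      for (gx in seq_len(g)) {
        if (i >= n) break
        i <- i + 1L
        placed <- FALSE
        for (t in 1:50) {
          cx <- (gx - 0.5) * sx + runif(1, -0.05, 0.05) * sx
          cy <- (gy - 0.5) * sy + runif(1, -0.05, 0.05) * sy
          a <- prior$cell_radius_um * runif(1, 0.85, 1.15)
          b <- prior$cell_radius_um * runif(1, 0.85, 1.15)
          a <- min(a, min(sx, sy) / 2 - margin)
          b <- min(b, min(sx, sy) / 2 - margin)
          if (add_cell(i, cx, cy, a, b, runif(1, 0, pi))) {
            placed <- TRUE
            break
          }
        }
        if (!placed) placement_error(sprintf("cell %d", i))
      }
    }
  } else {
    # restart the whole layout when an early cell blocks the rest
    done <- FALSE
    for (restart in 1:25) {
      cells <- list()
      cell_labels[] <- 0L
      failed <- FALSE
      for (i in seq_len(n)) {
        placed <- FALSE
        for (t in 1:500) {
          a <- prior$cell_radius_um * runif(1, 0.85, 1.15)
          b <- prior$cell_radius_um * runif(1, 0.85, 1.15)
          theta <- runif(1, 0, pi)
          rmax <- max(a, b)
          if (2 * (rmax + margin) >= min(W, H)) {
            placement_error(sprintf("cell %d (cell larger than field)", i))
          }
          cx <- runif(1, rmax + margin, W - rmax - margin)
          cy <- runif(1, rmax + margin, H - rmax - margin)
          if (add_cell(i, cx, cy, a, b, theta)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          failed <- TRUE
          break
        }
      }
      if (!failed) {
        done <- TRUE
        break
      }
    }
    if (!done) placement_error(sprintf("%d cells", n))
  }
  list(cells = bind_rows(lapply(cells, as_tibble)), cell_labels = cell_labels)
}

#' Generate a ground-truthed synthetic scene
#'
#' Lays out non-overlapping elliptical cells (one nucleus each), fills each
#' cell with mitochondrial components drawn from the prior's morphology class
#' mix -- sub-micrometre fragments ("dots"), unbranched tubules ("rods") and
#' branched tubule trees with at least one junction ("networks") -- and
#' scatters acidified red-only puncta (optionally lysosome-positive) and PLA
#' puncta. All ground truth (per-component skeleton geometry, total length,
#' junction count, true class; per-punctum position, cell and lysosome state)
#' is stored in the returned object, so downstream detection and
#' classification can be scored exactly.
#'
#' Generation is deterministic given `prior$seed`. Components are placed with
#' a minimum mutual separation so that distinct objects remain resolvable in
#' the rendered image; if the requested content cannot be placed, an error of
#' class `mitoquant_placement_error` is raised rather than silently dropping
#' objects.
#'
#' @param prior A [scene_prior()].
#' @return An object of class `synthetic_scene`: a list with tibbles `cells`,
#'   `components` (with list-column `geometry`), `puncta`, `pla`, the integer
#'   `cell_labels` mask, `image_shape` and `pixel_size_um`.
#' @seealso [render_image()], [write_scene_truth()], [rasterize_scene()]
#' @export
generate_scene <- function(prior) {
  if (!inherits(prior, "scene_prior")) {
    abort("`prior` must be created by scene_prior()")
  }
  with_seed(prior$seed, {
    shape <- prior$image_shape
    ps <- prior$pixel_size_um
    laid <- place_cells(prior)
    cells <- laid$cells
    occupied <- matrix(FALSE, shape[1L], shape[2L])
    sep <- prior$min_component_sep_um
    w <- prior$tubule_width_um
    comp_rows <- list()
    comp_geoms <- list()
    comp_id <- 0L
    mp <- morphology_params()

    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      counts <- if (!is.null(prior$class_counts)) {
        prior$class_counts
      } else {
        drawn <- rmultinom(1L, prior$n_components_per_cell,
                           prior$class_mix)[, 1L]
        setNames(drawn, names(prior$class_mix))
      }
      classes <- rep(c("dot", "rod", "network"),
                     counts[c("dot", "rod", "network")])
      for (cls in classes) {
        placed <- FALSE
        for (t in 1:400) {
          geom <- switch(cls,
            dot = sample_dot_geom(prior),
            rod = sample_rod_geom(prior),
            network = sample_network_geom(prior)
          )
          ctr <- sample_point_in_ellipse(
            cell$center_x_um, cell$center_y_um, cell$axis_a_um,
            cell$axis_b_um, cell$theta, shrink = w / 2 + 0.2
          )
          if (is.null(ctr)) next
          polys <- translate_polys(geom$polylines, ctr)
          pts <- do.call(rbind, lapply(polys, densify_polyline,
                                       step_um = ps))
          if (!all(in_ellipse(pts[, 1L], pts[, 2L], cell$center_x_um,
                              cell$center_y_um,
                              cell$axis_a_um - w / 2 - 0.2,
                              cell$axis_b_um - w / 2 - 0.2, cell$theta))) {
            next
          }
          foot <- unlist(lapply(polys, rasterize_polyline,
                                width_um = w + sep, pixel_size_um = ps,
                                shape = shape))
          foot <- unique(foot)
          if (any(occupied[foot])) next
          occupied[foot] <- TRUE
          comp_id <- comp_id + 1L
          total_len <- sum(vapply(polys, polyline_length_um, 0)) +
            geom$n_tips * w / 2
          true_class <- as.character(
            classify_component(total_len, geom$n_junctions, mp)
          )
          comp_rows[[comp_id]] <- tibble(
            component_id = comp_id, cell_id = cell$cell_id,
            true_class = true_class, true_total_length_um = total_len,
            true_n_junctions = geom$n_junctions
          )
          comp_geoms[[comp_id]] <- polys
          placed <- TRUE
          break
        }
        if (!placed) {
          placement_error(sprintf("a %s component in cell %d", cls,
                                  cell$cell_id))
        }
      }
    }

    components <- if (comp_id > 0L) {
      mutate(bind_rows(comp_rows), geometry = comp_geoms)
    } else {
      tibble(
        component_id = integer(), cell_id = integer(),
        true_class = character(), true_total_length_um = double(),
        true_n_junctions = integer(), geometry = list()
      )
    }

    place_puncta <- function(n_per_cell, radius_um, min_sep, avoid_mito,
                             label) {
      rows <- list()
      centers <- matrix(0, 0L, 2L)
      pid <- 0L
      for (ci in seq_len(nrow(cells))) {
        cell <- cells[ci, ]
        np <- n_per_cell[ci]
        for (j in seq_len(np)) {
          done <- FALSE
          for (t in 1:300) {
            pt <- sample_point_in_ellipse(
              cell$center_x_um, cell$center_y_um, cell$axis_a_um,
              cell$axis_b_um, cell$theta, shrink = radius_um + 0.1
            )
            if (is.null(pt)) break
            if (nrow(centers) > 0L &&
                min(sqrt((centers[, 1L] - pt[1L])^2 +
                         (centers[, 2L] - pt[2L])^2)) < min_sep) {
              next
            }
            if (avoid_mito) {
              foot <- rasterize_disc(pt[1L], pt[2L], radius_um + 0.3, ps,
                                     shape)
              if (any(occupied[foot])) next
            }
            pid <- pid + 1L
            centers <- rbind(centers, pt)
            rows[[pid]] <- tibble(
              punctum_id = pid, cell_id = cell$cell_id, x_um = pt[1L],
              y_um = pt[2L], radius_um = radius_um
            )
            done <- TRUE
            break
          }
          if (!done) placement_error(sprintf("%s punctum in cell %d", label,
                                             cell$cell_id))
        }
      }
      if (pid == 0L) {
        tibble(punctum_id = integer(), cell_id = integer(), x_um = double(),
               y_um = double(), radius_um = double())
      } else {
        bind_rows(rows)
      }
    }

    n_cells <- nrow(cells)
    pos <- if (n_cells > 0L) {
      rbinom(n_cells, 1L, prior$prob_red_only_cell)
    } else {
      integer()
    }
    mean_dots <- prior$n_red_only_per_cell_dist[["mean"]]
    n_red <- ifelse(pos == 1L,
                    1L + rpois(n_cells, max(0, mean_dots - 1)), 0L)
    puncta <- place_puncta(n_red, prior$red_only_radius_um,
                           prior$puncta_min_sep_um, avoid_mito = TRUE,
                           label = "red-only")
    puncta$lyso_positive <- if (nrow(puncta) > 0L) {
      rbinom(nrow(puncta), 1L, prior$lyso_colocalization_prob) == 1L
    } else {
      logical()
    }

    mean_pla <- prior$n_pla_per_cell_dist[["mean"]]
    pla <- if (mean_pla > 0 && n_cells > 0L) {
      place_puncta(rpois(n_cells, mean_pla), 0.15, 0.6, avoid_mito = FALSE,
                   label = "PLA")
    } else {
      tibble(punctum_id = integer(), cell_id = integer(), x_um = double(),
             y_um = double(), radius_um = double())
    }

    structure(
      list(
        cells = cells, cell_labels = laid$cell_labels,
        components = components, puncta = puncta, pla = pla,
        image_shape = shape, pixel_size_um = ps, prior = prior
      ),
      class = "synthetic_scene"
    )
  })
}

#' Rasterize ground-truth structure masks of a scene
#'
#' Renders the noiseless binary support of one structure class of a
#' [generate_scene()] scene at the scene's pixel grid. Used as the
#' ground-truth oracle when scoring segmentation and detection.
#'
#' @param scene A `synthetic_scene`.
#' @param what One of `"mito"` (all mitochondrial tubules, the EGFP support),
#'   `"red_only"`, `"lyso"` (lysosome-positive red-only puncta), `"nuclei"`,
#'   `"pla"`.
#' @return A logical matrix of the scene's `image_shape`.
#' @export
rasterize_scene <- function(scene,
                            what = c("mito", "red_only", "lyso", "nuclei",
                                     "pla")) {
  what <- match.arg(what)
  shape <- scene$image_shape
  ps <- scene$pixel_size_um
  out <- matrix(FALSE, shape[1L], shape[2L])
  idx <- switch(what,
    mito = unlist(lapply(scene$components$geometry, function(polys) {
      unlist(lapply(polys, rasterize_polyline,
                    width_um = scene$prior$tubule_width_um,
                    pixel_size_um = ps, shape = shape))
    })),
    red_only = unlist(lapply(seq_len(nrow(scene$puncta)), function(i) {
      p <- scene$puncta[i, ]
      rasterize_disc(p$x_um, p$y_um, p$radius_um, ps, shape)
    })),
    lyso = {
      lp <- scene$puncta[scene$puncta$lyso_positive, , drop = FALSE]
      unlist(lapply(seq_len(nrow(lp)), function(i) {
        p <- lp[i, ]
        rasterize_disc(p$x_um, p$y_um, p$radius_um * 1.3, ps, shape)
      }))
    },
    nuclei = unlist(lapply(seq_len(nrow(scene$cells)), function(i) {
      cc <- scene$cells[i, ]
      rasterize_disc(cc$nucleus_x_um, cc$nucleus_y_um, cc$nucleus_radius_um,
                     ps, shape)
    })),
    pla = unlist(lapply(seq_len(nrow(scene$pla)), function(i) {
      p <- scene$pla[i, ]
      rasterize_disc(p$x_um, p$y_um, p$radius_um, ps, shape)
    }))
  )
  if (length(idx) > 0L) {
    out[unique(idx)] <- TRUE
  }
  out
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px @ %.3f um/px: %d cells, %d components, %d red-only puncta (%d lyso+), %d PLA\n",
    x$image_shape[1L], x$image_shape[2L], x$pixel_size_um, nrow(x$cells),
    nrow(x$components), nrow(x$puncta), sum(x$puncta$lyso_positive),
    nrow(x$pla)
  ))
  if (nrow(x$components) > 0L) {
    tab <- table(x$components$true_class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
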