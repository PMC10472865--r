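# Shared fixtures: scenes are expensive, so they are memoised per argument
# set within a test run. All randomness is seeded through the generator.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

small_prior <- function(seed, ...) {
  args <- list(image_shape = c(320L, 320L), n_cells = 1L, cell_radius_um = 6,
               n_components_per_cell = 8, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_prior, args)
}

small_scene <- function(seed, ...) {
  args <- list(...)
  key <- paste0("scene_", seed, "_", paste(deparse(args), collapse = ""))
  cached(key, generate_scene(small_prior(seed, ...)))
}

# Greedy one-to-one matching of detections to ground-truth puncta within a
# distance tolerance; returns the number of true positives.
match_spots <- function(spots, truth, tol_um) {
  if (nrow(spots) == 0L || nrow(truth) == 0L) {
    return(0L)
  }
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(spots))) {
    d <- sqrt((truth$x_um - spots$x_um[i])^2 +
                (truth$y_um - spots$y_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= tol_um) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# Ground-truth puncta that survive the edge-exclusion rule.
truth_retained <- function(scene, margin_um = 1) {
  W <- scene$image_shape[2L] * scene$pixel_size_um
  H <- scene$image_shape[1L] * scene$pixel_size_um
  p <- scene$puncta
  d <- pmin(p$x_um, W - p$x_um, p$y_um, H - p$y_um)
  p[d >= margin_um, , drop = FALSE]
}

# Independent restatement of the morphology classification rules, written as
# a plain decision table (the implementation is interval logic over a
# factor); used as the rule oracle.
oracle_classify <- function(len, junc, res_limit = 0.25, dot_max = 1.0) {
  if (len < res_limit) {
    return("excluded")
  }
  if (len < dot_max) {
    return("dot")
  }
  if (junc >= 1) {
    return("network")
  }
  "rod"
}

# Brute-force pixel-degree analysis of a skeleton fixture, independent of
# the package's graph builder.
brute_degrees <- function(skel) {
  n <- which(skel, arr.ind = TRUE)
  deg <- integer(nrow(n))
  for (i in seq_len(nrow(n))) {
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r <- n[i, 1L] + dr
        c <- n[i, 2L] + dc
        if (r >= 1L && r <= nrow(skel) && c >= 1L && c <= ncol(skel) &&
            skel[r, c]) {
          deg[i] <- deg[i] + 1L
        }
      }
    }
  }
  deg
}

# Rasterized 1-px-wide straight segment from p0 along `angle` with length
# len_px, drawn by dense sampling (Bresenham-like).
raster_line <- function(shape, r0, c0, angle, len_px) {
  t <- seq(0, len_px, by = 0.25)
  rr <- round(r0 + t * sin(angle))
  cc <- round(c0 + t * cos(angle))
  m <- matrix(FALSE, shape[1L], shape[2L])
  keep <- rr >= 1 & rr <= shape[1L] & cc >= 1 & cc <= shape[2L]
  m[cbind(rr[keep], cc[keep])] <- TRUE
  m
}
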