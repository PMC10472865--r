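# Red-only puncta detection and per-cell quantification.
#
# The acidified-mitochondria readout of the tandem mCherry-EGFP reporter:
# a derived channel keeps mCherry signal only where it exceeds 1.5x the EGFP
# signal (EGFP is quenched at lysosomal pH), spots are detected in that
# channel at the ~0.5 um fragment scale with a Laplacian-of-Gaussian filter,
# spots within 1 um of the image edge are excluded, and counts are normalized
# per cell against DAPI-detected nuclei. The same spot machinery quantifies
# PLA puncta.

#' Puncta detection parameters
#'
#' @param redonly_factor A pixel is red-only when mCherry exceeds this factor
#'   times EGFP (default 1.5, i.e. mCherry 50% higher; the inequality is
#'   strict).
#' @param min_intensity Intensity floor on mCherry for the red-only rule, in
#'   counts; `NULL` (default) estimates it as median + 3 robust SDs of the
#'   mCherry channel, preventing red-only calls in near-zero-EGFP background.
#' @param spot_diameter_um Detection scale: expected punctum diameter (um,
#'   default 0.5, the size of an acidified mitochondrial fragment).
#' @param edge_margin_um Spots closer than this to any image border are
#'   excluded from all counts (um, default 1).
#' @param lyso_positive_threshold Mean lysosome-channel intensity above which
#'   a spot is lysosome-positive; `NULL` (default) uses median + 3 robust SDs
#'   of the LYSO channel.
#' @param detect_threshold_sd Peak detection threshold in units of the
#'   noise SD propagated through the detection filter (default 5).
#' @param size_gate_factor Reject detections whose equivalent diameter
#'   exceeds this multiple of `spot_diameter_um` (artifact gate; default
#'   2.5).
#' @return An object of class `puncta_params`.
#' @export
puncta_params <- function(redonly_factor = 1.5, min_intensity = NULL,
                          spot_diameter_um = 0.5, edge_margin_um = 1.0,
                          lyso_positive_threshold = NULL,
                          detect_threshold_sd = 5, size_gate_factor = 2.5) {
  stopifnot_scalar_num(redonly_factor, "redonly_factor", 1, strict = TRUE)
  stopifnot_scalar_num(spot_diameter_um, "spot_diameter_um", 0, strict = TRUE)
  stopifnot_scalar_num(edge_margin_um, "edge_margin_um", 0)
  if (!is.null(min_intensity)) {
    stopifnot_scalar_num(min_intensity, "min_intensity", 0)
  }
  structure(
    list(redonly_factor = redonly_factor, min_intensity = min_intensity,
         spot_diameter_um = spot_diameter_um,
         edge_margin_um = edge_margin_um,
         lyso_positive_threshold = lyso_positive_threshold,
         detect_threshold_sd = detect_threshold_sd,
         size_gate_factor = size_gate_factor),
    class = "puncta_params"
  )
}

#' Derive the red-only channel by channel arithmetic
#'
#' Keeps the mCherry intensity exactly where the mCherry signal is more than
#' `redonly_factor` times the EGFP signal (strictly) and at least the
#' `min_intensity` floor; all other pixels are zero. No other preprocessing
#' is applied.
#'
#' @param egfp,mcherry Numeric matrices of identical shape.
#' @param params A [puncta_params()].
#' @return Numeric matrix: the derived red-only channel.
#' @export
red_only_channel <- function(egfp, mcherry, params = puncta_params()) {
  if (!identical(dim(egfp), dim(mcherry))) {
    abort("EGFP and mCherry channels must have identical shape")
  }
  floor_int <- params$min_intensity
  if (is.null(floor_int)) {
    floor_int <- median(mcherry) + 3 * mad(mcherry)
  }
  keep <- (mcherry > params$redonly_factor * egfp) & (mcherry >= floor_int)
  out <- mcherry
  out[!keep] <- 0
  out
}

log_kernel <- function(sigma_px, dims) {
  size <- clamp_odd(2L * ceiling(4 * sigma_px) + 1L, dims)
  half <- (size - 1L) / 2L
  ax <- seq(-half, half)
  xs <- matrix(rep(ax, each = size), size)
  ys <- matrix(rep(ax, times = size), size)
  r2 <- xs^2 + ys^2
  g <- exp(-r2 / (2 * sigma_px^2))
  lg <- (r2 - 2 * sigma_px^2) / sigma_px^2 * g # sigma^2-normalized LoG
  lg <- lg - mean(lg)                          # zero response to flat input
  -lg / sum(g)                                 # positive peaks on bright blobs
}

#' Detect diffraction-limited spots in one channel
#'
#' Laplacian-of-Gaussian blob detection at the single scale set by
#' `spot_diameter_um`, with local-maximum selection and a detection threshold
#' expressed relative to the channel noise (robust SD propagated through the
#' filter). Deterministic. Detections much larger than the expected spot
#' size (see `size_gate_factor`) are rejected as artifacts.
#'
#' @param channel Non-negative numeric matrix.
#' @param pixel_size_um Pixel size (um).
#' @param params A [puncta_params()].
#' @param noise_sd Robust noise SD of the channel; `NULL` estimates it by
#'   MAD (falling back to the MAD of the non-zero pixels for sparse derived
#'   channels such as the red-only channel).
#' @return Tibble of spots: `spot_id`, `x_um`, `y_um`, `diameter_um`,
#'   `response`, `intensity_mean`, `edge_excluded` (initialized `FALSE`),
#'   `cell_id` (`NA`), `lyso_positive` (`NA`).
#' @export
detect_spots <- function(channel, pixel_size_um, params = puncta_params(),
                         noise_sd = NULL) {
  ps <- pixel_size_um
  empty <- tibble(
    spot_id = integer(), x_um = double(), y_um = double(),
    diameter_um = double(), response = double(), intensity_mean = double(),
    edge_excluded = logical(), cell_id = integer(), lyso_positive = logical()
  )
  if (all(channel <= 0)) {
    return(empty)
  }
  sigma_px <- params$spot_diameter_um / 2 / sqrt(2) / ps
  k <- log_kernel(sigma_px, dim(channel))
  resp <- as.matrix(imageData(filter2(channel, k, boundary = "circular")))
  if (is.null(noise_sd)) {
    noise_sd <- mad(channel)
    if (noise_sd <= 0) {
      nz <- channel[channel > 0]
      noise_sd <- if (length(nz) > 1L) mad(nz) else 0
    }
  }
  thr <- max(params$detect_threshold_sd * noise_sd * sqrt(sum(k^2)),
             0.05 * max(resp), 1e-12)
  win <- clamp_odd(round(params$spot_diameter_um / ps), dim(channel))
  mx <- as.matrix(imageData(EBImage::dilate(resp, makeBrush(win, "disc"))))
  peaks <- which(resp >= mx & resp > thr)
  if (length(peaks) == 0L) {
    return(empty)
  }
  rc <- arrayInd(peaks, dim(resp))
  ord <- order(resp[peaks], decreasing = TRUE)
  rc <- rc[ord, , drop = FALSE]
  # non-maximum suppression of plateau duplicates within one spot radius
  min_sep_px <- params$spot_diameter_um / 2 / ps
  keep <- rep(TRUE, nrow(rc))
  for (i in seq_len(nrow(rc))) {
    if (!keep[i]) next
    if (i < nrow(rc)) {
      j <- (i + 1L):nrow(rc)
      d <- sqrt((rc[j, 1L] - rc[i, 1L])^2 + (rc[j, 2L] - rc[i, 2L])^2)
      keep[j[d < min_sep_px]] <- FALSE
    }
  }
  rc <- rc[keep, , drop = FALSE]
  r_px <- params$spot_diameter_um / 2 / ps
  off_meas <- disc_offsets(r_px)
  off_cent <- disc_offsets(max(1, round(r_px)))
  nr <- nrow(channel)
  nc <- ncol(channel)
  rows <- double(0)
  cols <- double(0)
  responses <- double(0)
  means <- double(0)
  for (i in seq_len(nrow(rc))) {
    r0 <- rc[i, 1L]
    c0 <- rc[i, 2L]
    # intensity-weighted subpixel centroid of the response
    rr <- r0 + off_cent[, 1L]
    cc <- c0 + off_cent[, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    wts <- pmax(resp[cbind(rr[ok], cc[ok])], 0)
    if (sum(wts) <= 0) {
      wr <- r0
      wc <- c0
    } else {
      wr <- sum(rr[ok] * wts) / sum(wts)
      wc <- sum(cc[ok] * wts) / sum(wts)
    }
    # size gate: support of the response above half the peak
    area_px <- sum(resp[cbind(rr[ok], cc[ok])] > 0.5 * resp[r0, c0])
    eq_diam_um <- 2 * sqrt(area_px / pi) * ps
    if (eq_diam_um > params$size_gate_factor * params$spot_diameter_um) {
      next
    }
    rrm <- r0 + off_meas[, 1L]
    ccm <- c0 + off_meas[, 2L]
    okm <- rrm >= 1L & rrm <= nr & ccm >= 1L & ccm <= nc
    rows <- c(rows, wr)
    cols <- c(cols, wc)
    responses <- c(responses, resp[r0, c0])
    means <- c(means, mean(channel[cbind(rrm[okm], ccm[okm])]))
  }
  if (length(rows) == 0L) {
    return(empty)
  }
  um <- px_to_um(rows, cols, ps)
  tibble(
    spot_id = seq_along(rows), x_um = um[, 1L], y_um = um[, 2L],
    diameter_um = params$spot_diameter_um, response = responses,
    intensity_mean = means, edge_excluded = FALSE, cell_id = NA_integer_,
    lyso_positive = NA
  )
}

#' Flag spots near the image border
#'
#' Flags spots whose centroid lies within `edge_margin_um` of any image
#' border; flagged spots are omitted from all downstream counts.
#'
#' @param spots Spot tibble from [detect_spots()].
#' @param image_shape `c(ny, nx)` in pixels.
#' @param pixel_size_um Pixel size (um).
#' @param params A [puncta_params()].
#' @return `spots` with `edge_excluded` set.
#' @export
exclude_edge_spots <- function(spots, image_shape, pixel_size_um,
                               params = puncta_params()) {
  if (nrow(spots) == 0L) {
    return(spots)
  }
  H <- image_shape[1L] * pixel_size_um
  W <- image_shape[2L] * pixel_size_um
  d <- pmin(spots$x_um, W - spots$x_um, spots$y_um, H - spots$y_um)
  spots$edge_excluded <- d < params$edge_margin_um
  spots
}

#' Detect nuclei in the DAPI channel
#'
#' Smooth, threshold (Otsu with a blank-frame contrast guard), fill holes,
#' split touching nuclei by watershed on the distance map, and filter small
#' objects. One seed per nucleus; the seed count is the frame's cell count.
#'
#' @param dapi Numeric matrix (DAPI channel).
#' @param pixel_size_um Pixel size (um).
#' @param smooth_sigma_um Smoothing sigma (um, default 0.4).
#' @param min_area_um2 Minimum nucleus area kept (um^2, default 3).
#' @return List with `nuclei` (tibble `cell_id`, `x_um`, `y_um`, `area_um2`)
#'   and `labels` (integer matrix of nucleus masks).
#' @export
detect_nuclei <- function(dapi, pixel_size_um, smooth_sigma_um = 0.4,
                          min_area_um2 = 3) {
  ps <- pixel_size_um
  sm <- blur_gaussian(dapi, smooth_sigma_um / ps, boundary = "replicate")
  bin <- threshold_foreground(sm)
  empty <- list(
    nuclei = tibble(cell_id = integer(), x_um = double(), y_um = double(),
                    area_um2 = double()),
    labels = matrix(0L, nrow(dapi), ncol(dapi))
  )
  if (!any(bin)) {
    return(empty)
  }
  bin <- imageData(fillHull(bin)) > 0
  dm <- distmap(bin)
  labels <- imageData(watershed(dm))
  storage.mode(labels) <- "integer"
  labels <- filter_small_objects(labels, min_area_um2 / ps^2)
  if (max(labels) == 0L) {
    return(empty)
  }
  n <- max(labels)
  idx <- which(labels > 0L)
  rc <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  rows <- tapply(rc[, 1L], lab, mean)
  cols <- tapply(rc[, 2L], lab, mean)
  areas <- tabulate(lab, nbins = n) * ps^2
  um <- px_to_um(as.numeric(rows), as.numeric(cols), ps)
  list(
    nuclei = tibble(cell_id = seq_len(n), x_um = um[, 1L], y_um = um[, 2L],
                    area_um2 = areas),
    labels = labels
  )
}

#' Assign spots to cells
#'
#' Each spot is assigned to the cell whose mask contains it (when
#' `cell_labels` is given) and otherwise to the nearest nucleus centroid;
#' distance ties are broken by the lowest `cell_id`.
#'
#' @param spots Spot tibble.
#' @param nuclei Nuclei tibble from [detect_nuclei()].
#' @param cell_labels Optional integer matrix of cytoplasmic cell masks.
#' @param pixel_size_um Pixel size (needed with `cell_labels`).
#' @return `spots` with `cell_id` filled (NA when there are no cells).
#' @export
assign_spots_to_cells <- function(spots, nuclei, cell_labels = NULL,
                                  pixel_size_um = NULL) {
  if (nrow(spots) == 0L) {
    return(spots)
  }
  if (nrow(nuclei) == 0L) {
    spots$cell_id <- NA_integer_
    return(spots)
  }
  nuclei <- nuclei[order(nuclei$cell_id), , drop = FALSE]
  nearest <- function(x, y) {
    d <- sqrt((nuclei$x_um - x)^2 + (nuclei$y_um - y)^2)
    nuclei$cell_id[which.min(d)] # ties: first (lowest cell_id)
  }
  ids <- integer(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    id <- NA_integer_
    if (!is.null(cell_labels)) {
      px <- round(um_to_px(spots$x_um[i], spots$y_um[i], pixel_size_um))
      px[1L] <- min(max(px[1L], 1L), nrow(cell_labels))
      px[2L] <- min(max(px[2L], 1L), ncol(cell_labels))
      lab <- cell_labels[px[1L], px[2L]]
      if (lab > 0L) {
        id <- lab
      }
    }
    if (is.na(id)) {
      id <- nearest(spots$x_um[i], spots$y_um[i])
    }
    ids[i] <- id
  }
  spots$cell_id <- ids
  spots
}

#' Per-frame red-only quantification
#'
#' Computes the frame-level statistics used as statistical datapoints: the
#' percentage of cells containing red-only dots, the mean number of dots per
#' positive cell (dots counted only over cells that have any), and the mean
#' number of dots per total cells. Edge-excluded spots are omitted. A frame
#' with zero detected cells is flagged invalid.
#'
#' @param spots Spot tibble (after edge exclusion and cell assignment).
#' @param n_cells Number of cells (nuclei) in the frame.
#' @param frame_id Frame identifier.
#' @return One-row tibble: `frame_id`, `valid`, `n_cells`, `n_spots`,
#'   `n_cells_with_red_only`, `pct_cells_with_red_only`,
#'   `dots_per_positive_cell`, `dots_per_total_cells`.
#' @export
quantify_frame <- function(spots, n_cells, frame_id = 1L) {
  if (n_cells < 0) {
    abort("`n_cells` must be >= 0")
  }
  if (n_cells == 0L) {
    return(tibble(
      frame_id = frame_id, valid = FALSE, n_cells = 0L, n_spots = NA_integer_,
      n_cells_with_red_only = NA_integer_,
      pct_cells_with_red_only = NA_real_, dots_per_positive_cell = NA_real_,
      dots_per_total_cells = NA_real_
    ))
  }
  kept <- spots[!spots$edge_excluded & !is.na(spots$cell_id), , drop = FALSE]
  total <- nrow(kept)
  n_pos <- dplyr::n_distinct(kept$cell_id)
  tibble(
    frame_id = frame_id, valid = TRUE, n_cells = as.integer(n_cells),
    n_spots = total, n_cells_with_red_only = n_pos,
    pct_cells_with_red_only = 100 * n_pos / n_cells,
    dots_per_positive_cell = if (n_pos > 0L) total / n_pos else NA_real_,
    dots_per_total_cells = total / n_cells
  )
}

#' Lysosome colocalization of detected spots
#'
#' Fraction of retained spots whose mean lysosome-channel intensity within
#' one spot radius exceeds the positivity threshold; also sets each spot's
#' `lyso_positive` flag.
#'
#' @param spots Spot tibble.
#' @param lyso Numeric matrix (lysosome-marker channel).
#' @param pixel_size_um Pixel size (um).
#' @param params A [puncta_params()]; `lyso_positive_threshold = NULL` uses
#'   median + 3 robust SDs of `lyso`.
#' @return List with `fraction` (over retained spots) and the updated
#'   `spots`.
#' @export
colocalization_fraction <- function(spots, lyso, pixel_size_um,
                                    params = puncta_params()) {
  if (is.null(lyso)) {
    abort("LYSO channel missing")
  }
  thr <- params$lyso_positive_threshold
  if (is.null(thr)) {
    thr <- median(lyso) + 3 * mad(lyso)
  }
  if (nrow(spots) == 0L) {
    return(list(fraction = NA_real_, spots = spots))
  }
  ps <- pixel_size_um
  nr <- nrow(lyso)
  nc <- ncol(lyso)
  flag <- rep(NA, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    off <- disc_offsets(spots$diameter_um[i] / 2 / ps)
    px <- round(um_to_px(spots$x_um[i], spots$y_um[i], ps))
    rr <- px[1L] + off[, 1L]
    cc <- px[2L] + off[, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    flag[i] <- mean(lyso[cbind(rr[ok], cc[ok])]) > thr
  }
  spots$lyso_positive <- flag
  kept <- !spots$edge_excluded
  list(fraction = mean(flag[kept]), spots = spots)
}

bilinear_sample <- function(mat, row, col) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L)
  c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0
  fc <- col - c0
  mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    mat[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Intensity line profile across all channels
#'
#' Bilinearly interpolates every channel at `n_samples` evenly spaced points
#' between two image positions, e.g. across a red-only punctum to display
#' mCherry/EGFP/lysosome colocalization.
#'
#' @param img A `multichannel_image`.
#' @param p0,p1 Endpoints `c(x_um, y_um)`; must lie inside the image.
#' @param n_samples Number of sample points (default 100).
#' @return Tibble of class `line_profile`: `distance_um`, `channel`,
#'   `intensity`.
#' @export
line_profile <- function(img, p0, p1, n_samples = 100L) {
  d <- dim(img$data)
  ps <- img$pixel_size_um
  W <- d[2L] * ps
  H <- d[1L] * ps
  for (p in list(p0, p1)) {
    if (length(p) != 2L || p[1L] < 0 || p[1L] > W || p[2L] < 0 ||
        p[2L] > H) {
      abort("profile endpoints must lie inside the image")
    }
  }
  t <- if (n_samples == 1L) 0.5 else seq(0, 1, length.out = n_samples)
  xs <- p0[1L] + t * (p1[1L] - p0[1L])
  ys <- p0[2L] + t * (p1[2L] - p0[2L])
  px <- um_to_px(xs, ys, ps)
  dist <- sqrt((xs - xs[1L])^2 + (ys - ys[1L])^2)
  out <- lapply(img$channel_names, function(ch) {
    tibble(
      distance_um = dist, channel = ch,
      intensity = bilinear_sample(get_channel(img, ch), px[, 1L], px[, 2L])
    )
  })
  res <- bind_rows(out)
  class(res) <- c("line_profile", class(res))
  res
}

#' Full red-only quantification of one frame
#'
#' The complete per-frame pipeline: derive the red-only channel
#' ([red_only_channel()]), detect spots ([detect_spots()]), exclude edge
#' spots, detect nuclei ([detect_nuclei()]), assign spots to cells, measure
#' lysosome colocalization when a LYSO channel is present, and quantify the
#' frame ([quantify_frame()]).
#'
#' @param img A `multichannel_image` with EGFP, mCherry and DAPI channels
#'   (LYSO optional).
#' @param params A [puncta_params()].
#' @param frame_id Frame identifier.
#' @return List of class `mitophagy_quant`: `frame` (one-row tibble, plus
#'   `lyso_fraction`), `spots`, `nuclei`, `red_only` (the derived channel).
#' @export
quantify_mitophagy <- function(img, params = puncta_params(),
                               frame_id = 1L) {
  ps <- img$pixel_size_um
  ro <- red_only_channel(get_channel(img, "EGFP"),
                         get_channel(img, "mCherry"), params)
  spots <- detect_spots(ro, ps, params)
  spots <- exclude_edge_spots(spots, dim(ro), ps, params)
  nuc <- detect_nuclei(get_channel(img, "DAPI"), ps)
  spots <- assign_spots_to_cells(spots, nuc$nuclei)
  lyso_fraction <- NA_real_
  if ("LYSO" %in% img$channel_names && nrow(spots) > 0L) {
    cl <- colocalization_fraction(spots, get_channel(img, "LYSO"), ps,
                                  params)
    spots <- cl$spots
    lyso_fraction <- cl$fraction
  }
  frame <- quantify_frame(spots, nrow(nuc$nuclei), frame_id)
  frame$lyso_fraction <- lyso_fraction
  structure(
    list(frame = frame, spots = spots, nuclei = nuc$nuclei, red_only = ro),
    class = "mitophagy_quant"
  )
}

#' Quantify PLA puncta per cell
#'
#' Reuses the spot machinery on a proximity-ligation (PLA) channel and
#' normalizes counts per cell.
#'
#' @param img A `multichannel_image` with PLA and DAPI channels.
#' @param params A [puncta_params()] (a smaller `spot_diameter_um`, e.g.
#'   0.3, suits typical PLA puncta).
#' @param frame_id Frame identifier.
#' @return One-row tibble: `frame_id`, `valid`, `n_cells`, `n_pla_puncta`,
#'   `n_pla_puncta_per_cell`.
#' @export
quantify_pla <- function(img, params = puncta_params(spot_diameter_um = 0.3),
                         frame_id = 1L) {
  ps <- img$pixel_size_um
  spots <- detect_spots(get_channel(img, "PLA"), ps, params)
  spots <- exclude_edge_spots(spots, dim(img$data)[1:2], ps, params)
  nuc <- detect_nuclei(get_channel(img, "DAPI"), ps)
  spots <- assign_spots_to_cells(spots, nuc$nuclei)
  n_cells <- nrow(nuc$nuclei)
  kept <- sum(!spots$edge_excluded & !is.na(spots$cell_id))
  tibble(
    frame_id = frame_id, valid = n_cells > 0L, n_cells = n_cells,
    n_pla_puncta = kept,
    n_pla_puncta_per_cell = if (n_cells > 0L) kept / n_cells else NA_real_
  )
}

#' @export
print.mitophagy_quant <- function(x, ...) {
  f <- x$frame
  cat(sprintf(
    "<mitophagy_quant> frame %s: %d cells, %d red-only dots; %.1f%% cells positive, %.2f dots/positive cell, %.2f dots/total cells\n",
    format(f$frame_id), f$n_cells, f$n_spots, f$pct_cells_with_red_only,
    f$dots_per_positive_cell, f$dots_per_total_cells
  ))
  invisible(x)
}
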