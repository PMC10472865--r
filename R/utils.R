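# Internal helpers shared across modules.

# Evaluate `code` with the RNG temporarily seeded; restores the caller's RNG
# state afterwards so library calls never disturb user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Largest odd kernel size that fits the image.
clamp_odd <- function(size, dims) {
  size <- max(3L, as.integer(size))
  if (size %% 2L == 0L) size <- size + 1L
  lim <- min(dims)
  if (size > lim) {
    size <- if (lim %% 2L == 1L) lim else lim - 1L
    size <- max(size, 1L)
  }
  size
}

gaussian_kernel <- function(sigma_px, size) {
  half <- (size - 1L) / 2L
  ax <- seq(-half, half)
  g <- exp(-ax^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian blur via FFT convolution. Circular boundary conserves the image
# sum (used for PSF rendering); replicate boundary is translation-consistent
# under tiling (used for segmentation smoothing).
blur_gaussian <- function(mat, sigma_px, boundary = "circular") {
  if (sigma_px <= 0) {
    return(mat)
  }
  size <- clamp_odd(2L * ceiling(3 * sigma_px) + 1L, dim(mat))
  if (size < 3L) {
    return(mat)
  }
  k <- gaussian_kernel(sigma_px, size)
  as.matrix(imageData(filter2(mat, k, boundary = boundary)))
}

# FWHM (um) -> Gaussian sigma in pixels.
fwhm_to_sigma_px <- function(fwhm_um, pixel_size_um) {
  fwhm_um / (2 * sqrt(2 * log(2))) / pixel_size_um
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s %s", name, if (strict) ">" else ">=", format(lower)
    ))
  }
  invisible(x)
}

# Linear indices of a filled disc stamped at (rows, cols) pixel centres.
disc_offsets <- function(radius_px) {
  r <- max(0, radius_px)
  ri <- ceiling(r)
  dr <- rep(seq(-ri, ri), times = 2L * ri + 1L)
  dc <- rep(seq(-ri, ri), each = 2L * ri + 1L)
  keep <- dr^2 + dc^2 <= r^2 + 1e-9
  cbind(dr[keep], dc[keep])
}

stamp_points <- function(rows, cols, radius_px, shape) {
  off <- disc_offsets(radius_px)
  rows <- round(rows)
  cols <- round(cols)
  rr <- outer(rows, off[, 1L], "+")
  cc <- outer(cols, off[, 2L], "+")
  keep <- rr >= 1L & rr <= shape[1L] & cc >= 1L & cc <= shape[2L]
  unique((cc[keep] - 1L) * shape[1L] + rr[keep])
}

# Resample a polyline (n x 2 matrix of um coords) at ~step_um spacing.
densify_polyline <- function(poly_um, step_um) {
  if (nrow(poly_um) < 2L) {
    return(poly_um)
  }
  out <- list()
  for (i in seq_len(nrow(poly_um) - 1L)) {
    p0 <- poly_um[i, ]
    p1 <- poly_um[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    nseg <- max(1L, ceiling(len / step_um))
    t <- seq(0, 1, length.out = nseg + 1L)
    seg <- cbind(p0[1L] + t * (p1[1L] - p0[1L]), p0[2L] + t * (p1[2L] - p0[2L]))
    out[[i]] <- if (i == 1L) seg else seg[-1L, , drop = FALSE]
  }
  do.call(rbind, out)
}

polyline_length_um <- function(poly_um) {
  if (is.null(poly_um) || nrow(poly_um) < 2L) {
    return(0)
  }
  sum(sqrt(rowSums(diff(poly_um)^2)))
}

# um coords (x, y) -> fractional pixel (row, col); pixel (1,1) centre is
# (0.5, 0.5) * pixel_size.
um_to_px <- function(x_um, y_um, pixel_size_um) {
  cbind(row = y_um / pixel_size_um + 0.5, col = x_um / pixel_size_um + 0.5)
}

px_to_um <- function(row, col, pixel_size_um) {
  cbind(x_um = (col - 0.5) * pixel_size_um, y_um = (row - 0.5) * pixel_size_um)
}

# Pixel indices covered by a polyline drawn with a given stroke width.
rasterize_polyline <- function(poly_um, width_um, pixel_size_um, shape) {
  pts <- densify_polyline(poly_um, step_um = pixel_size_um / 2)
  px <- um_to_px(pts[, 1L], pts[, 2L], pixel_size_um)
  stamp_points(px[, 1L], px[, 2L], radius_px = width_um / 2 / pixel_size_um,
               shape = shape)
}

rasterize_disc <- function(x_um, y_um, radius_um, pixel_size_um, shape) {
  px <- um_to_px(x_um, y_um, pixel_size_um)
  stamp_points(px[, 1L], px[, 2L], radius_px = radius_um / pixel_size_um,
               shape = shape)
}
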