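# Image formation: rasterized structure -> Gaussian PSF -> photon scaling ->
# Poisson shot noise -> Gaussian read noise -> background -> clipping.

#' Construct a multi-channel image
#'
#' @param data Numeric array `(ny, nx, n_channels)` (or `(ny, nx, nc, nz)`
#'   for a z-stack) of non-negative intensities.
#' @param channel_names Character vector of unique channel labels (e.g.
#'   `"EGFP"`, `"mCherry"`, `"LYSO"`, `"DAPI"`, `"PLA"`).
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(data, channel_names, pixel_size_um) {
  if (length(dim(data)) == 2L) {
    data <- array(data, dim = c(dim(data), 1L))
  }
  if (!length(dim(data)) %in% c(3L, 4L)) {
    abort("`data` must be a (ny, nx, nc[, nz]) array")
  }
  if (dim(data)[3L] != length(channel_names)) {
    abort("third dimension of `data` must match length(channel_names)")
  }
  if (anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique")
  }
  if (any(data < 0)) {
    abort("intensities must be non-negative")
  }
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  dimnames(data)[[3L]] <- channel_names
  structure(
    list(data = data, channel_names = channel_names,
         pixel_size_um = pixel_size_um),
    class = "multichannel_image"
  )
}

#' Extract one channel as a matrix
#'
#' Z-stacks are maximum-intensity projected, matching the convention that
#' quantification operates on max projections.
#'
#' @param img A `multichannel_image`.
#' @param channel Channel name.
#' @return Numeric matrix `(ny, nx)`.
#' @export
get_channel <- function(img, channel) {
  if (!inherits(img, "multichannel_image")) {
    abort("`img` must be a multichannel_image")
  }
  if (!channel %in% img$channel_names) {
    abort(sprintf("channel '%s' not present (have: %s)", channel,
                  paste(img$channel_names, collapse = ", ")))
  }
  k <- match(channel, img$channel_names)
  d <- img$data
  if (length(dim(d)) == 4L) {
    apply(d[, , k, , drop = FALSE], c(1L, 2L), max)
  } else {
    d[, , k]
  }
}

#' Maximum-intensity projection of a z-stack
#'
#' @param img A `multichannel_image` (4D). 2D images are returned unchanged.
#' @return A 2D `multichannel_image`.
#' @export
max_project <- function(img) {
  if (length(dim(img$data)) == 3L) {
    return(img)
  }
  proj <- apply(img$data, c(1L, 2L, 3L), max)
  multichannel_image(proj, img$channel_names, img$pixel_size_um)
}

render_channel_structure <- function(scene, channel) {
  shape <- scene$image_shape
  ps <- scene$pixel_size_um
  out <- matrix(0, shape[1L], shape[2L])
  add_disc <- function(out, x, y, r, amp) {
    idx <- rasterize_disc(x, y, r, ps, shape)
    out[idx] <- out[idx] + amp
    out
  }
  if (channel %in% c("EGFP", "mCherry")) {
    idx <- unlist(lapply(scene$components$geometry, function(polys) {
      unlist(lapply(polys, rasterize_polyline,
                    width_um = scene$prior$tubule_width_um,
                    pixel_size_um = ps, shape = shape))
    }))
    if (length(idx) > 0L) {
      out[unique(idx)] <- 1
    }
  }
  if (channel == "mCherry") {
    for (i in seq_len(nrow(scene$puncta))) {
      p <- scene$puncta[i, ]
      out <- add_disc(out, p$x_um, p$y_um, p$radius_um, 2)
    }
  }
  if (channel == "LYSO") {
    lp <- scene$puncta[scene$puncta$lyso_positive, , drop = FALSE]
    for (i in seq_len(nrow(lp))) {
      p <- lp[i, ]
      out <- add_disc(out, p$x_um, p$y_um, p$radius_um * 1.3, 1.5)
    }
  }
  if (channel == "DAPI") {
    for (i in seq_len(nrow(scene$cells))) {
      cc <- scene$cells[i, ]
      out <- add_disc(out, cc$nucleus_x_um, cc$nucleus_y_um,
                      cc$nucleus_radius_um, 1)
    }
  }
  if (channel == "PLA") {
    for (i in seq_len(nrow(scene$pla))) {
      p <- scene$pla[i, ]
      out <- add_disc(out, p$x_um, p$y_um, p$radius_um, 2)
    }
  }
  out
}

#' Render a synthetic scene into a multi-channel fluorescence image
#'
#' Rasterizes the scene's structures into per-channel intensity maps --
#' neutral mitochondria into both EGFP and mCherry (the tandem reporter is
#' yellow on neutral organelles), red-only puncta into mCherry only (EGFP is
#' quenched in acidic compartments), lysosome-positive puncta into LYSO,
#' nuclei into DAPI, PLA puncta into PLA -- then applies the optical and
#' camera model of [optics_params()]: Gaussian PSF convolution (circular
#' boundary, photon-conserving), scaling by `photons_per_unit`, Poisson shot
#' noise, additive Gaussian read noise, constant background, and clipping to
#' the camera bit depth.
#'
#' @param scene A `synthetic_scene`.
#' @param optics An [optics_params()]; its `pixel_size_um` should equal the
#'   scene's (the scene grid wins, with a warning on mismatch).
#' @param seed Integer seed for the noise draws (`NULL` uses the current RNG
#'   state). Identical scene, optics and seed give bit-identical images.
#' @param n_slices Odd number of z-slices; 1 (default) renders a single
#'   plane. For stacks, the central slice is in focus and defocused slices
#'   are rendered with a PSF widened by `defocus_fwhm_um_per_um` per
#'   micrometre of axial offset.
#' @param slice_spacing_um Axial spacing of the stack (um).
#' @param defocus_fwhm_um_per_um Axial blur growth rate.
#' @return A `multichannel_image` with channels EGFP, mCherry, LYSO, DAPI
#'   (and PLA when the scene contains PLA puncta).
#' @export
render_image <- function(scene, optics = optics_params(), seed = NULL,
                         n_slices = 1L, slice_spacing_um = 0.3,
                         defocus_fwhm_um_per_um = 0.6) {
  if (!inherits(scene, "synthetic_scene")) {
    abort("`scene` must be created by generate_scene()")
  }
  if (!inherits(optics, "optics_params")) {
    abort("`optics` must be created by optics_params()")
  }
  ps <- scene$pixel_size_um
  if (abs(optics$pixel_size_um - ps) > 1e-12) {
    warn("optics pixel_size_um differs from the scene grid; using the scene's")
  }
  if (optics$psf_fwhm_um > 0 && optics$psf_fwhm_um < ps) {
    warn("PSF FWHM below the pixel size: the PSF is undersampled")
  }
  channels <- c("EGFP", "mCherry", "LYSO", "DAPI")
  if (nrow(scene$pla) > 0L) {
    channels <- c(channels, "PLA")
  }
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L || n_slices %% 2L == 0L) {
    abort("`n_slices` must be an odd positive integer")
  }
  structs <- lapply(channels, function(ch) render_channel_structure(scene, ch))
  names(structs) <- channels
  max_count <- 2^optics$bit_depth - 1

  render_plane <- function(struct, fwhm_um) {
    s <- struct
    if (fwhm_um > 0) {
      s <- blur_gaussian(s, fwhm_to_sigma_px(fwhm_um, ps))
    }
    expected <- optics$photons_per_unit * s
    counts <- if (optics$shot_noise) {
      matrix(rpois(length(expected), pmax(expected, 0)), nrow(expected))
    } else {
      expected
    }
    counts <- counts + optics$background
    if (optics$read_noise_sd > 0) {
      counts <- counts + matrix(rnorm(length(counts), 0,
                                      optics$read_noise_sd), nrow(counts))
    }
    pmin(pmax(counts, 0), max_count)
  }

  with_seed(seed, {
    if (n_slices == 1L) {
      planes <- lapply(structs, render_plane, fwhm_um = optics$psf_fwhm_um)
      data <- array(unlist(planes), dim = c(scene$image_shape,
                                            length(channels)))
    } else {
      half <- (n_slices - 1L) / 2L
      data <- array(0, dim = c(scene$image_shape, length(channels),
                               n_slices))
      for (zi in seq_len(n_slices)) {
        dz <- abs(zi - half - 1L) * slice_spacing_um
        fwhm <- sqrt(optics$psf_fwhm_um^2 + (defocus_fwhm_um_per_um * dz)^2)
        for (k in seq_along(channels)) {
          data[, , k, zi] <- render_plane(structs[[k]], fwhm)
        }
      }
    }
    multichannel_image(data, channels, ps)
  })
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$data)
  zdesc <- if (length(d) == 4L) sprintf(", %d z-slices", d[4L]) else ""
  cat(sprintf("<multichannel_image> %d x %d px @ %.3f um/px%s; channels: %s\n",
              d[1L], d[2L], x$pixel_size_um, zdesc,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}
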