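#' Optical and camera model parameters
#'
#' Describes the image-formation model used by [render_image()]: an isotropic
#' Gaussian point-spread function (PSF), linear photon scaling, Poisson shot
#' noise, additive Gaussian read noise and a constant background offset, on a
#' square pixel grid.
#'
#' @param pixel_size_um Pixel size in micrometres (default 0.05, i.e. 50 nm,
#'   the Airyscan-scale sampling used for live-cell reporter imaging).
#' @param psf_fwhm_um Full width at half maximum of the Gaussian PSF in
#'   micrometres; 0 disables blurring (default 0.25, confocal-scale).
#' @param photons_per_unit Expected photon count produced by structure of unit
#'   intensity (default 200).
#' @param read_noise_sd Standard deviation of additive Gaussian read noise, in
#'   counts (default 2).
#' @param background Constant background offset, in counts (default 10).
#' @param bit_depth Camera bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]` (default 16).
#' @param shot_noise Logical; apply Poisson sampling to the expected photon
#'   image? Setting `FALSE` (together with `read_noise_sd = 0`) yields the
#'   deterministic expected image.
#'
#' @return An object of class `optics_params`.
#' @seealso [ideal_optics()] for the noise- and blur-free setting used in
#'   ground-truth recovery checks.
#' @export
optics_params <- function(pixel_size_um = 0.05, psf_fwhm_um = 0.25,
                          photons_per_unit = 200, read_noise_sd = 2,
                          background = 10, bit_depth = 16L,
                          shot_noise = TRUE) {
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  stopifnot_scalar_num(psf_fwhm_um, "psf_fwhm_um", 0)
  stopifnot_scalar_num(photons_per_unit, "photons_per_unit", 0)
  stopifnot_scalar_num(read_noise_sd, "read_noise_sd", 0)
  stopifnot_scalar_num(background, "background", 0)
  stopifnot_scalar_num(bit_depth, "bit_depth", 1)
  structure(
    list(
      pixel_size_um = pixel_size_um, psf_fwhm_um = psf_fwhm_um,
      photons_per_unit = photons_per_unit, read_noise_sd = read_noise_sd,
      background = background, bit_depth = as.integer(bit_depth),
      shot_noise = isTRUE(shot_noise)
    ),
    class = "optics_params"
  )
}

#' Noise-free, blur-free optics
#'
#' Convenience constructor for the idealized imaging model (no PSF, no shot or
#' read noise, zero background) under which a rendered image equals the scaled
#' rasterized structure exactly. Used to test ground-truth recovery of the
#' analysis independently of noise.
#'
#' @inheritParams optics_params
#' @param photons_per_unit Intensity scale of the ideal render (default 100).
#' @return An object of class `optics_params`.
#' @export
ideal_optics <- function(pixel_size_um = 0.05, photons_per_unit = 100) {
  optics_params(
    pixel_size_um = pixel_size_um, psf_fwhm_um = 0,
    photons_per_unit = photons_per_unit, read_noise_sd = 0, background = 0,
    shot_noise = FALSE
  )
}

#' Scene prior for the synthetic-image generator
#'
#' Parameterizes the ground-truthed scenes produced by [generate_scene()]:
#' how many cells to lay out, the mix of mitochondrial morphology classes
#' (dots, rods, networks), the length distributions of rods and network
#' branches, and the per-cell statistics of acidified "red-only" puncta and
#' their lysosome colocalization.
#'
#' Morphology classes follow the skeleton-based rules of
#' [classify_component()]: rods are single unbranched tubules longer than
#' 1 um, networks are branched tubule trees with at least one junction, dots
#' are sub-micrometre fragments. `rod_min_length_um` keeps generated rod
#' lengths clear of the 1 um dot/rod boundary so that every generated object
#' has a well-defined true class at the rendering resolution.
#'
#' @param image_shape Integer vector `c(ny, nx)` in pixels.
#' @param pixel_size_um Pixel size of the scene grid (um).
#' @param n_cells Number of cells to place.
#' @param layout `"random"` (rejection-sampled positions) or `"grid"`
#'   (jittered grid, for dense fields of many cells).
#' @param cell_radius_um Nominal cell radius (um); each cell is an ellipse
#'   with axes drawn within +/-15% of this value.
#' @param nucleus_radius_um Nucleus radius (um). Nuclei are placed so that no
#'   two are closer than one nucleus diameter edge-to-edge.
#' @param class_mix Named fractions `c(dot=, rod=, network=)` summing to 1;
#'   per-cell class counts are drawn multinomially from this mix.
#' @param class_counts Optional named integer vector of exact per-cell counts
#'   `c(dot=, rod=, network=)`; overrides `class_mix` and
#'   `n_components_per_cell`.
#' @param n_components_per_cell Mitochondrial components per cell.
#' @param rod_length_dist `c(mean, sd)` of the rod length distribution (um),
#'   truncated below at `rod_min_length_um`.
#' @param rod_min_length_um Hard lower truncation for rod lengths (um).
#' @param network_branch_count_dist `c(min, max)` branches radiating from a
#'   network junction.
#' @param network_branch_length_dist `c(mean, sd)` of network branch lengths
#'   (um), truncated below at 0.7 um (so each branch stays resolvable at the
#'   rendered tubule width).
#' @param dot_diameter_um Extent of a dot-class fragment (um).
#' @param tubule_width_um Rendered tubule stroke width (um).
#' @param min_component_sep_um Minimum surface-to-surface separation between
#'   distinct components (um), so rendered components stay resolvable.
#' @param n_red_only_per_cell_dist `c(mean)` red-only puncta per positive
#'   cell; counts are 1 + Poisson(mean - 1) so positives have at least one.
#' @param prob_red_only_cell Probability that a cell contains any red-only
#'   puncta.
#' @param red_only_radius_um Radius of a red-only punctum (um).
#' @param puncta_min_sep_um Minimum centre-to-centre separation between
#'   puncta (um).
#' @param lyso_colocalization_prob Probability that a red-only punctum is
#'   lysosome-marker positive.
#' @param n_pla_per_cell_dist `c(mean)` proximity-ligation (PLA) puncta per
#'   cell (Poisson); 0 disables the PLA channel.
#' @param seed Integer seed; scenes are bit-identical for identical priors
#'   and seeds.
#'
#' @return An object of class `scene_prior`.
#' @export
scene_prior <- function(image_shape = c(512L, 512L), pixel_size_um = 0.05,
                        n_cells = 2, layout = c("random", "grid"),
                        cell_radius_um = 6, nucleus_radius_um = 2.5,
                        class_mix = c(dot = 0.1, rod = 0.2, network = 0.7),
                        class_counts = NULL, n_components_per_cell = 8,
                        rod_length_dist = c(mean = 2.0, sd = 0.5),
                        rod_min_length_um = 1.2,
                        network_branch_count_dist = c(min = 3L, max = 5L),
                        network_branch_length_dist = c(mean = 0.9, sd = 0.2),
                        dot_diameter_um = 0.5, tubule_width_um = 0.2,
                        min_component_sep_um = 0.4,
                        n_red_only_per_cell_dist = c(mean = 2),
                        prob_red_only_cell = 0.5, red_only_radius_um = 0.25,
                        puncta_min_sep_um = 1.0,
                        lyso_colocalization_prob = 0.9,
                        n_pla_per_cell_dist = c(mean = 0), seed = 1L) {
  layout <- match.arg(layout)
  if (length(image_shape) != 2L || any(image_shape < 16)) {
    abort("`image_shape` must be c(ny, nx) with both >= 16 pixels")
  }
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  stopifnot_scalar_num(n_cells, "n_cells", 0)
  stopifnot_scalar_num(dot_diameter_um, "dot_diameter_um", 0, strict = TRUE)
  stopifnot_scalar_num(tubule_width_um, "tubule_width_um", 0, strict = TRUE)
  stopifnot_scalar_num(rod_min_length_um, "rod_min_length_um", 0, strict = TRUE)
  if (!all(c("dot", "rod", "network") %in% names(class_mix))) {
    abort("`class_mix` must be named with dot, rod, network")
  }
  class_mix <- class_mix[c("dot", "rod", "network")]
  if (any(class_mix < 0) || any(class_mix > 1) ||
      abs(sum(class_mix) - 1) > 1e-9) {
    abort("`class_mix` fractions must lie in [0, 1] and sum to 1")
  }
  if (!is.null(class_counts)) {
    if (!all(c("dot", "rod", "network") %in% names(class_counts)) ||
        any(class_counts < 0)) {
      abort("`class_counts` must be non-negative, named dot/rod/network")
    }
    class_counts <- as.integer(class_counts[c("dot", "rod", "network")])
    names(class_counts) <- c("dot", "rod", "network")
  }
  if (prob_red_only_cell < 0 || prob_red_only_cell > 1) {
    abort("`prob_red_only_cell` must lie in [0, 1]")
  }
  if (lyso_colocalization_prob < 0 || lyso_colocalization_prob > 1) {
    abort("`lyso_colocalization_prob` must lie in [0, 1]")
  }
  structure(
    list(
      image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
      n_cells = as.integer(n_cells), layout = layout,
      cell_radius_um = cell_radius_um, nucleus_radius_um = nucleus_radius_um,
      class_mix = class_mix, class_counts = class_counts,
      n_components_per_cell = as.integer(n_components_per_cell),
      rod_length_dist = rod_length_dist,
      rod_min_length_um = rod_min_length_um,
      network_branch_count_dist = as.integer(network_branch_count_dist),
      network_branch_length_dist = network_branch_length_dist,
      dot_diameter_um = dot_diameter_um, tubule_width_um = tubule_width_um,
      min_component_sep_um = min_component_sep_um,
      n_red_only_per_cell_dist = n_red_only_per_cell_dist,
      prob_red_only_cell = prob_red_only_cell,
      red_only_radius_um = red_only_radius_um,
      puncta_min_sep_um = puncta_min_sep_um,
      lyso_colocalization_prob = lyso_colocalization_prob,
      n_pla_per_cell_dist = n_pla_per_cell_dist, seed = as.integer(seed)
    ),
    class = "scene_prior"
  )
}
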