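# Morphology classification of skeletonized mitochondria: dots, rods,
# networks, by total skeleton branch length and junction count.

#' Morphology classification parameters
#'
#' @param dot_max_length_um Length below which a component is a dot (um,
#'   default 1.0). Components of exactly this length are rods/networks (the
#'   half-open convention: dots are strictly shorter than 1 um).
#' @param resolution_limit_um Components shorter than this are excluded as
#'   unresolvable segmentation noise (um, default 0.25, confocal-scale).
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(dot_max_length_um = 1.0,
                              resolution_limit_um = 0.25) {
  stopifnot_scalar_num(dot_max_length_um, "dot_max_length_um", 0,
                       strict = TRUE)
  stopifnot_scalar_num(resolution_limit_um, "resolution_limit_um", 0,
                       strict = TRUE)
  if (resolution_limit_um >= dot_max_length_um) {
    abort("`resolution_limit_um` must be smaller than `dot_max_length_um`")
  }
  structure(
    list(dot_max_length_um = dot_max_length_um,
         resolution_limit_um = resolution_limit_um),
    class = "morphology_params"
  )
}

#' Classify a mitochondrial component from its skeleton
#'
#' Applies the skeleton-based morphology rules: components shorter than the
#' microscope resolution limit are `excluded`; remaining components shorter
#' than 1 um are `dot`s; longer components are `rod`s when their skeleton has
#' no junction and `network`s when it has at least one. Vectorized and pure:
#' the class is a deterministic function of `(total_length_um, n_junctions)`
#' and the parameters.
#'
#' @param total_length_um Total skeleton branch length of the component (um).
#' @param n_junctions Number of skeleton junctions (nodes of degree >= 3).
#' @param params A [morphology_params()].
#' @return Factor with levels `excluded`, `dot`, `rod`, `network`.
#' @export
classify_component <- function(total_length_um, n_junctions,
                               params = morphology_params()) {
  if (any(!is.finite(total_length_um)) || any(total_length_um < 0)) {
    abort("`total_length_um` must be finite and >= 0")
  }
  if (any(!is.finite(n_junctions)) || any(n_junctions < 0)) {
    abort("`n_junctions` must be finite and >= 0")
  }
  n <- max(length(total_length_um), length(n_junctions))
  total_length_um <- rep_len(total_length_um, n)
  n_junctions <- rep_len(n_junctions, n)
  out <- character(n)
  out[total_length_um < params$resolution_limit_um] <- "excluded"
  sel <- out == ""
  out[sel & total_length_um < params$dot_max_length_um] <- "dot"
  sel <- out == ""
  out[sel & n_junctions == 0] <- "rod"
  out[out == ""] <- "network"
  factor(out, levels = c("excluded", "dot", "rod", "network"))
}

#' Per-frame morphology summary
#'
#' Normalizes the morphology classification per image frame: class fractions
#' are computed over the included (non-excluded) components of one frame, and
#' mean lengths are reported for rods and networks separately.
#'
#' @param components Tibble with columns `frame_id`, `class`,
#'   `total_length_um` (as returned by [morphology_pipeline()]).
#' @param frame_id Frame identifier; may be omitted when `components`
#'   carries a single frame_id. Mixing frames is an error.
#' @return One-row tibble: `frame_id`, `n_included`, `fraction_dot`,
#'   `fraction_rod`, `fraction_network`, `mean_length_rod_um`,
#'   `mean_length_network_um`. Fractions are `NA` when `n_included` is 0.
#' @export
summarize_frame <- function(components, frame_id = NULL) {
  ids <- unique(components$frame_id)
  if (is.null(frame_id)) {
    if (length(ids) > 1L) {
      abort("`components` mixes several frame_ids; pass them one frame at a time")
    }
    frame_id <- if (length(ids) == 1L) ids else NA
  } else if (length(ids) > 0L && !all(ids == frame_id)) {
    abort("`components` contains rows from a different frame_id")
  }
  cls <- as.character(components$class)
  inc <- cls != "excluded"
  n_inc <- sum(inc)
  frac <- function(k) if (n_inc > 0L) sum(cls[inc] == k) / n_inc else NA_real_
  mean_len <- function(k) {
    v <- components$total_length_um[cls == k]
    if (length(v) > 0L) mean(v) else NA_real_
  }
  tibble(
    frame_id = frame_id, n_included = n_inc,
    fraction_dot = frac("dot"), fraction_rod = frac("rod"),
    fraction_network = frac("network"),
    mean_length_rod_um = mean_len("rod"),
    mean_length_network_um = mean_len("network")
  )
}

# Measure labelled components from the skeleton graph, with an optional
# medial-axis endpoint correction: thinning retracts a branch end to the
# medial axis, about half a tubule width short of the object boundary, so the
# mask's distance-transform value at each terminal skeleton pixel is added
# back. A single-pixel skeleton gets twice its distance value (the equivalent
# diameter of the blob). For compact blobs whose skeleton degenerates to a
# couple of pixels the corrected skeleton can still under-measure the true
# extent, so the moment-based major-axis length of the mask (the ellipse
# normalization, 4 * sqrt(lambda_1)) serves as a lower bound on each
# component's length.
measure_components <- function(mask, graph, endpoint_correction = TRUE) {
  ps <- mask$pixel_size_um
  n_comp <- mask$n_objects
  if (n_comp == 0L) {
    return(tibble(component_id = integer(), total_length_um = double(),
                  n_junctions = integer()))
  }
  lens <- numeric(n_comp)
  juncs <- integer(n_comp)
  cl <- component_lengths(graph)
  lens[cl$component] <- cl$total_length_um
  juncs[cl$component] <- cl$n_junctions
  if (endpoint_correction) {
    # lengths are sums of steps between pixel centres, so the extension from
    # a terminal skeleton pixel to the furthest foreground pixel centre is
    # the distance-transform value minus one pixel
    dt <- pmax(as.matrix(imageData(distmap(mask$labels > 0L))) - 1, 0) * ps
    ends <- graph$nodes[graph$nodes$degree <= 1L, , drop = FALSE]
    if (nrow(ends) > 0L) {
      vals <- dt[cbind(round(ends$row), round(ends$col))]
      # isolated pixels (degree 0) count twice: their full equivalent extent
      vals <- vals * ifelse(ends$degree == 0L, 2, 1)
      add <- tapply(vals, ends$component, sum)
      lens[as.integer(names(add))] <- lens[as.integer(names(add))] +
        as.numeric(add)
    }
    idx <- which(mask$labels > 0L)
    rc <- arrayInd(idx, dim(mask$labels))
    lab <- mask$labels[idx]
    major <- vapply(seq_len(n_comp), function(k) {
      pts <- rc[lab == k, , drop = FALSE]
      if (nrow(pts) < 2L) {
        return(ps)
      }
      n_px <- nrow(pts)
      cv <- stats::cov(pts) * (n_px - 1) / n_px + diag(1 / 12, 2L)
      l1 <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
      # solid-stroke (rectangle) normalization, in steps not pixels
      max(sqrt(12 * l1) - 1, 1) * ps
    }, 0)
    lens <- pmax(lens, major)
  }
  tibble(component_id = seq_len(n_comp), total_length_um = lens,
         n_junctions = juncs)
}

#' Segment, skeletonize and classify mitochondria in one frame
#'
#' Composition of [segment_mitochondria()], [skeletonize_mask()] (with spur
#' pruning at the resolution limit), per-component length/junction
#' measurement (with medial-axis endpoint correction) and
#' [classify_component()], normalized per frame by [summarize_frame()].
#'
#' @param img A `multichannel_image`.
#' @param seg_params Named list of arguments forwarded to
#'   [segment_mitochondria()].
#' @param morph_params A [morphology_params()].
#' @param frame_id Frame identifier attached to results.
#' @param endpoint_correction Apply the medial-axis endpoint length
#'   correction (default `TRUE`).
#' @return List with `components` (tibble: `component_id`, `frame_id`,
#'   `total_length_um`, `n_junctions`, `class`), `summary` (one-row tibble
#'   from [summarize_frame()]), and the intermediate `mask` and `graph`.
#' @export
morphology_pipeline <- function(img, seg_params = list(),
                                morph_params = morphology_params(),
                                frame_id = 1L,
                                endpoint_correction = TRUE) {
  mask <- do.call(segment_mitochondria, c(list(img = img), seg_params))
  graph <- skeletonize_mask(mask,
                            prune_spur_um = morph_params$resolution_limit_um)
  comps <- measure_components(mask, graph, endpoint_correction)
  comps$frame_id <- rep(frame_id, nrow(comps))
  comps$class <- classify_component(comps$total_length_um, comps$n_junctions,
                                    morph_params)
  comps <- comps[, c("component_id", "frame_id", "total_length_um",
                     "n_junctions", "class")]
  list(components = comps, summary = summarize_frame(comps, frame_id),
       mask = mask, graph = graph)
}
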