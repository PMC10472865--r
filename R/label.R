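# Connected-component labelling. EBImage::bwlabel is 4-connected; skeleton
# and mask analysis here follow the standard 8-connected convention, so
# 4-connected labels are merged across diagonal adjacencies with union-find.

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Label connected components (8-connected)
#'
#' @param binary Logical or 0/1 matrix.
#' @return Integer matrix with background 0 and components labelled 1..k
#'   consecutively.
#' @export
label_connected <- function(binary) {
  binary <- binary > 0
  if (!any(binary)) {
    return(matrix(0L, nrow(binary), ncol(binary)))
  }
  lab <- imageData(bwlabel(binary))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab > 1L) {
    parent <- seq_len(nlab)
    nr <- nrow(lab)
    nc <- ncol(lab)
    # diagonal neighbour pairs: (r, c) with (r + 1, c + 1) and (r + 1, c - 1)
    for (d in list(c(1L, 1L), c(1L, -1L))) {
      r0 <- 1L:(nr - 1L)
      c0 <- if (d[2L] == 1L) 1L:(nc - 1L) else 2L:nc
      a <- lab[r0, c0, drop = FALSE]
      b <- lab[r0 + 1L, c0 + d[2L], drop = FALSE]
      sel <- a > 0L & b > 0L & a != b
      if (any(sel)) {
        pairs <- unique(cbind(a[sel], b[sel]))
        for (i in seq_len(nrow(pairs))) {
          ra <- uf_find(parent, pairs[i, 1L])
          rb <- uf_find(parent, pairs[i, 2L])
          if (ra != rb) {
            parent[max(ra, rb)] <- min(ra, rb)
          }
        }
      }
    }
    roots <- vapply(seq_len(nlab), function(i) uf_find(parent, i), 1L)
    remap <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Label mask container
#'
#' @param labels Integer matrix; 0 is background, components are labelled
#'   1..k consecutively.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um) {
  storage.mode(labels) <- "integer"
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) > 0L && !identical(u, seq_along(u))) {
    labels[labels > 0L] <- match(labels[labels > 0L], u)
  }
  structure(
    list(labels = labels, pixel_size_um = pixel_size_um,
         n_objects = if (length(labels)) max(labels) else 0L),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px @ %.3f um/px, %d objects\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um, x$n_objects))
  invisible(x)
}

# Drop labelled objects below a pixel-area threshold and relabel.
filter_small_objects <- function(labels, min_area_px) {
  if (max(labels) == 0L || min_area_px <= 1) {
    return(labels)
  }
  areas <- tabulate(labels[labels > 0L], nbins = max(labels))
  drop <- which(areas < min_area_px)
  if (length(drop) > 0L) {
    labels[labels %in% drop] <- 0L
    u <- sort(unique(labels[labels > 0L]))
    if (length(u) > 0L) {
      labels[labels > 0L] <- match(labels[labels > 0L], u)
    }
  }
  labels
}
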