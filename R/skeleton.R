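# Skeletonization and skeleton-graph measurement.
#
# A binary mask is thinned to a one-pixel-wide 8-connected skeleton
# (Guo-Hall), then converted to a graph whose nodes are skeleton pixels of
# degree != 2 (endpoints, junctions, isolated pixels) and whose edges are the
# traced pixel paths between them. Branch lengths use the standard chamfer
# metric: pixel_size_um per axial step, sqrt(2) * pixel_size_um per diagonal
# step. Adjacent junction pixels (thinning doublets) are merged into a single
# junction node; optional spur pruning removes terminal branches shorter than
# a resolution limit.

#' Thin a binary mask to a one-pixel skeleton
#'
#' Guo-Hall iterative thinning (two-subiteration parallel algorithm),
#' followed by a staircase-corner cleanup; preserves 8-connectivity and line
#' endpoints and leaves a minimal 8-connected skeleton.
#'
#' @param binary Logical or 0/1 matrix.
#' @return Logical matrix of the same shape.
#' @export
thin_mask <- function(binary) {
  nr <- nrow(binary)
  nc <- ncol(binary)
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2L:(nr + 1L), 2L:(nc + 1L)] <- binary > 0
  ri <- 2L:(nr + 1L)
  ci <- 2L:(nc + 1L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- M[ri - 1L, ci]
      p3 <- M[ri - 1L, ci + 1L]
      p4 <- M[ri, ci + 1L]
      p5 <- M[ri + 1L, ci + 1L]
      p6 <- M[ri + 1L, ci]
      p7 <- M[ri + 1L, ci - 1L]
      p8 <- M[ri, ci - 1L]
      p9 <- M[ri - 1L, ci - 1L]
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (sub == 1L) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      cond <- M[ri, ci] & C == 1L & N >= 2L & N <= 3L & !m
      if (any(cond)) {
        Mi <- M[ri, ci]
        Mi[cond] <- FALSE
        M[ri, ci] <- Mi
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  remove_corner_pixels(M[ri, ci])
}

# Parallel thinning can leave staircase corners: pixels whose only two
# neighbours sit at orthogonal positions and are diagonally adjacent to each
# other, so the corner duplicates a path the diagonal already provides.
# Such corners inflate pixel degrees around junctions. Removing them swaps
# two axial steps for one diagonal step without retracting any endpoint, and
# removal cannot cascade (a neighbour of a removed corner is left with a
# mixed orthogonal/diagonal pair). Sequential raster-order passes until
# stable; deterministic.
remove_corner_pixels <- function(skel) {
  nr <- nrow(skel)
  nc <- ncol(skel)
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2L:(nr + 1L), 2L:(nc + 1L)] <- skel
  # neighbour vector order: NW, N, NE, W, E, SW, S, SE;
  # orthogonal positions are N = 2, W = 4, E = 5, S = 7
  ortho_pairs <- list(c(2L, 4L), c(2L, 5L), c(7L, 4L), c(7L, 5L))
  repeat {
    idx <- which(M)
    if (length(idx) == 0L) break
    rcs <- arrayInd(idx, dim(M))
    removed <- FALSE
    for (i in seq_along(idx)) {
      r <- rcs[i, 1L]
      cc <- rcs[i, 2L]
      if (!M[r, cc]) next
      nb <- c(M[r - 1L, cc - 1L], M[r - 1L, cc], M[r - 1L, cc + 1L],
              M[r, cc - 1L], M[r, cc + 1L],
              M[r + 1L, cc - 1L], M[r + 1L, cc], M[r + 1L, cc + 1L])
      if (sum(nb) != 2L) next
      hit <- FALSE
      for (pp in ortho_pairs) {
        if (nb[pp[1L]] && nb[pp[2L]]) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        M[r, cc] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  M[2L:(nr + 1L), 2L:(nc + 1L)]
}

# Eight-neighbour offsets (row, col).
.nbr_offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                   dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Convert a labelled mask to a skeleton graph
#'
#' Thins the mask ([thin_mask()]), traces branches between skeleton nodes,
#' merges adjacent junction pixels into single junction nodes, optionally
#' prunes terminal spurs shorter than `prune_spur_um` (a spur that is a
#' component's only branch is never pruned), and splices pass-through nodes
#' left by pruning.
#'
#' @param mask A [label_mask()] (or binary matrix plus `pixel_size_um`).
#' @param pixel_size_um Pixel size; only needed when `mask` is a bare matrix.
#' @param prune_spur_um Prune terminal branches shorter than this (um);
#'   0 disables pruning.
#' @return An object of class `skeleton_graph` with tibbles `nodes`
#'   (`node_id`, `row`, `col`, `degree`, `is_junction`, `component`) and
#'   `edges` (`edge_id`, `node_from`, `node_to`, `component`, `length_um`,
#'   `n_pixels`, list-column `path` of pixel coordinates).
#' @export
skeletonize_mask <- function(mask, pixel_size_um = NULL, prune_spur_um = 0) {
  if (inherits(mask, "label_mask")) {
    labels <- mask$labels
    ps <- mask$pixel_size_um
  } else {
    if (is.null(pixel_size_um)) {
      abort("`pixel_size_um` is required when `mask` is a bare matrix")
    }
    labels <- label_connected(mask)
    ps <- pixel_size_um
  }
  skel <- thin_mask(labels > 0L)
  build_skeleton_graph(skel, labels, ps, prune_spur_um)
}

build_skeleton_graph <- function(skel, comp_labels, ps, prune_spur_um = 0) {
  empty <- function() {
    structure(list(
      nodes = tibble(node_id = integer(), row = double(), col = double(),
                     degree = integer(), is_junction = logical(),
                     component = integer()),
      edges = tibble(edge_id = integer(), node_from = integer(),
                     node_to = integer(), component = integer(),
                     length_um = double(), n_pixels = integer(),
                     path = list()),
      pixel_size_um = ps, skeleton = skel
    ), class = "skeleton_graph")
  }
  p <- which(skel)
  if (length(p) == 0L) {
    return(empty())
  }
  nr <- nrow(skel)
  rc <- arrayInd(p, dim(skel))
  pr <- rc[, 1L]
  pc <- rc[, 2L]
  n <- length(p)
  map <- matrix(0L, nr + 2L, ncol(skel) + 2L)
  map[cbind(pr + 1L, pc + 1L)] <- seq_len(n)
  nbr <- matrix(0L, n, 8L)
  for (k in 1:8) {
    nbr[, k] <- map[cbind(pr + 1L + .nbr_offs[k, 1L],
                          pc + 1L + .nbr_offs[k, 2L])]
  }
  deg <- rowSums(nbr > 0L)
  comp <- comp_labels[p]
  is_node <- deg != 2L
  # pure cycles: skeleton components without any degree != 2 pixel
  for (cid in setdiff(unique(comp), unique(comp[is_node]))) {
    is_node[which(comp == cid)[1L]] <- TRUE
  }

  step_um <- function(i, j) {
    if (abs(pr[i] - pr[j]) + abs(pc[i] - pc[j]) == 2L) sqrt(2) * ps else ps
  }

  used <- matrix(FALSE, n, 8L)
  slot_of <- function(at, target) which(nbr[at, ] == target)[1L]
  edges_from <- integer()
  edges_to <- integer()
  edges_path <- list()
  ne <- 0L
  for (u in which(is_node)) {
    for (k in which(nbr[u, ] > 0L)) {
      if (used[u, k]) next
      used[u, k] <- TRUE
      v <- nbr[u, k]
      path <- c(u, v)
      prev <- u
      while (!is_node[v]) {
        nbrs <- nbr[v, ]
        nbrs <- nbrs[nbrs > 0L]
        nxt <- nbrs[nbrs != prev][1L]
        prev <- v
        v <- nxt
        path <- c(path, v)
      }
      used[v, slot_of(v, prev)] <- TRUE
      ne <- ne + 1L
      edges_from[ne] <- u
      edges_to[ne] <- v
      edges_path[[ne]] <- path
    }
  }

  # merge 8-adjacent junction pixels (thinning doublets) into one node
  jun <- is_node & deg >= 3L
  node_px <- which(is_node)
  cluster <- seq_len(n)
  for (u in which(jun)) {
    for (v in nbr[u, ]) {
      if (v > 0L && jun[v]) {
        ru <- uf_find(cluster, u)
        rv <- uf_find(cluster, v)
        if (ru != rv) cluster[max(ru, rv)] <- min(ru, rv)
      }
    }
  }
  roots <- vapply(node_px, function(i) uf_find(cluster, i), 1L)
  uroot <- unique(roots)
  node_of_px <- integer(n)
  node_of_px[node_px] <- match(roots, uroot)
  n_nodes <- length(uroot)
  node_row <- vapply(seq_len(n_nodes),
                     function(i) mean(pr[node_px[node_of_px[node_px] == i]]),
                     0)
  node_col <- vapply(seq_len(n_nodes),
                     function(i) mean(pc[node_px[node_of_px[node_px] == i]]),
                     0)
  node_comp <- vapply(seq_len(n_nodes),
                      function(i) comp[node_px[node_of_px[node_px] == i][1L]],
                      0L)
  node_isj <- vapply(seq_len(n_nodes),
                     function(i) any(jun[node_px[node_of_px[node_px] == i]]),
                     TRUE)

  ed <- list(
    node_from = node_of_px[edges_from],
    node_to = node_of_px[edges_to],
    path = edges_path
  )
  # drop 1-2 step artifact edges internal to one junction cluster
  if (ne > 0L) {
    keep <- !(ed$node_from == ed$node_to &
                vapply(ed$path, length, 1L) <= 3L &
                node_isj[ed$node_from])
    ed$node_from <- ed$node_from[keep]
    ed$node_to <- ed$node_to[keep]
    ed$path <- ed$path[keep]
  }
  path_len_um <- function(path) {
    if (length(path) < 2L) return(0)
    sum(vapply(seq_len(length(path) - 1L),
               function(i) step_um(path[i], path[i + 1L]), 0))
  }
  ed$length_um <- vapply(ed$path, path_len_um, 0)
  ed$component <- node_comp[ed$node_from]

  node_degree <- function(ed, n_nodes) {
    tabulate(c(ed$node_from, ed$node_to), nbins = n_nodes)
  }

  # prune short terminal spurs (never a component's only edge)
  if (prune_spur_um > 0 && length(ed$length_um) > 0L) {
    repeat {
      degs <- node_degree(ed, n_nodes)
      ncomp_edges <- table(ed$component)
      spur <- which(
        ed$length_um < prune_spur_um &
          (degs[ed$node_from] == 1L | degs[ed$node_to] == 1L) &
          as.vector(ncomp_edges[as.character(ed$component)]) > 1L
      )
      if (length(spur) == 0L) break
      drop <- spur[which.min(ed$length_um[spur])]
      for (f in c("node_from", "node_to", "path", "length_um", "component")) {
        ed[[f]] <- ed[[f]][-drop]
      }
      # splice pass-through nodes left behind
      repeat {
        degs <- node_degree(ed, n_nodes)
        mid <- which(degs == 2L & node_isj)
        spliced <- FALSE
        for (m in mid) {
          inc <- which(ed$node_from == m | ed$node_to == m)
          if (length(inc) != 2L) next # self-loop at m
          e1 <- inc[1L]
          e2 <- inc[2L]
          # orient e1 to end at m, e2 to start at m
          if (ed$node_from[e1] == m) {
            ed$node_from[e1] <- ed$node_to[e1]
            ed$path[[e1]] <- rev(ed$path[[e1]])
          }
          if (ed$node_to[e2] == m) {
            ed$node_to[e2] <- ed$node_from[e2]
            ed$path[[e2]] <- rev(ed$path[[e2]])
          }
          ed$node_to[e1] <- ed$node_to[e2]
          ed$path[[e1]] <- c(ed$path[[e1]],
                             ed$path[[e2]][-1L])
          ed$length_um[e1] <- path_len_um(ed$path[[e1]])
          for (f in c("node_from", "node_to", "path", "length_um",
                      "component")) {
            ed[[f]] <- ed[[f]][-e2]
          }
          node_isj[m] <- FALSE
          spliced <- TRUE
          break
        }
        if (!spliced) break
      }
    }
  }

  degs <- node_degree(ed, n_nodes)
  nodes <- tibble(
    node_id = seq_len(n_nodes), row = node_row, col = node_col,
    degree = as.integer(degs), is_junction = node_isj & degs >= 3L,
    component = as.integer(node_comp)
  )
  n_edges <- length(ed$length_um)
  paths <- lapply(ed$path, function(path) cbind(row = pr[path],
                                                col = pc[path]))
  edges <- tibble(
    edge_id = seq_len(n_edges),
    node_from = as.integer(ed$node_from), node_to = as.integer(ed$node_to),
    component = as.integer(ed$component), length_um = ed$length_um,
    n_pixels = vapply(ed$path, length, 1L), path = paths
  )
  structure(
    list(nodes = nodes, edges = edges, pixel_size_um = ps, skeleton = skel),
    class = "skeleton_graph"
  )
}

#' Count junctions in one skeleton component
#'
#' A junction is a merged cluster of skeleton pixels of degree >= 3; a
#' component with at least one junction is topologically branched.
#'
#' @param graph A [skeletonize_mask()] result.
#' @param component_id Component label in the source mask.
#' @return Integer junction count.
#' @export
count_junctions <- function(graph, component_id) {
  known <- unique(c(graph$nodes$component, graph$edges$component))
  if (!component_id %in% known) {
    abort(sprintf("unknown component %s", format(component_id)))
  }
  sum(graph$nodes$is_junction & graph$nodes$component == component_id)
}

#' Per-component skeleton summary
#'
#' @param graph A `skeleton_graph`.
#' @return A tibble with one row per component: `component`,
#'   `total_length_um` (sum of branch lengths), `n_junctions`, `n_edges`,
#'   `n_endpoints`.
#' @export
component_lengths <- function(graph) {
  comps <- sort(unique(graph$nodes$component))
  tibble(
    component = comps,
    total_length_um = vapply(comps, function(cid) {
      sum(graph$edges$length_um[graph$edges$component == cid])
    }, 0),
    n_junctions = vapply(comps, function(cid) {
      count_junctions(graph, cid)
    }, 0L),
    n_edges = vapply(comps, function(cid) {
      sum(graph$edges$component == cid)
    }, 0L),
    n_endpoints = vapply(comps, function(cid) {
      sum(graph$nodes$component == cid & graph$nodes$degree <= 1L)
    }, 0L)
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d nodes, %d edges, %d components @ %.3f um/px\n",
    nrow(x$nodes), nrow(x$edges),
    length(unique(x$nodes$component)), x$pixel_size_um
  ))
  invisible(x)
}
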