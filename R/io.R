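# Image and ground-truth I/O: multi-page TIFF with a JSON metadata sidecar
# (channel names, pixel size, bit depth), plus CSV ground-truth tables.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel image to TIFF
#'
#' Channels are stored as 16-bit pages of a multi-page TIFF; channel names,
#' pixel size (um) and bit depth are stored in a JSON sidecar next to the
#' image (`<path>.json`). Z-stacks are max-projected before writing.
#'
#' @param img A `multichannel_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(img, path) {
  img <- max_project(img)
  max_count <- 2^16 - 1
  pages <- lapply(seq_along(img$channel_names), function(k) {
    pmin(pmax(img$data[, , k], 0), max_count) / max_count
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(
      channel_names = img$channel_names,
      pixel_size_um = img$pixel_size_um,
      physical_size_x_um = img$pixel_size_um,
      physical_size_y_um = img$pixel_size_um,
      bit_depth = 16L,
      image_shape = dim(img$data)[1:2]
    ),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multi-channel image written by [write_multichannel_tiff()]
#'
#' @param path TIFF path (the JSON sidecar must sit next to it).
#' @return A `multichannel_image`.
#' @export
read_multichannel_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) {
    pages <- list(pages)
  }
  max_count <- 2^16 - 1
  data <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) {
    data[, , k] <- pages[[k]] * max_count
  }
  multichannel_image(data, meta$channel_names, meta$pixel_size_um)
}

write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) {
    abort("label mask exceeds uint16 range")
  }
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_label_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write scene ground truth to disk
#'
#' Writes the tabular ground truth of a [generate_scene()] scene -- one CSV
#' each for components, puncta and cells -- plus uint16 label-mask TIFFs for
#' the cell layout and the binary mitochondrial structure, and a JSON file
#' with the scene geometry (shape, pixel size). An empty scene produces
#' headers-only CSVs and zero-filled masks.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_truth <- function(scene, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(sprintf("cannot create directory '%s'", dir))
    }
  }
  comps <- scene$components
  comps$geometry <- NULL
  readr::write_csv(comps, file.path(dir, "components.csv"))
  readr::write_csv(scene$puncta, file.path(dir, "puncta.csv"))
  readr::write_csv(scene$pla, file.path(dir, "pla.csv"))
  readr::write_csv(scene$cells, file.path(dir, "cells.csv"))
  write_label_tiff(scene$cell_labels, file.path(dir, "cell_labels.tif"))
  write_label_tiff(rasterize_scene(scene, "mito") * 1L,
                   file.path(dir, "mito_mask.tif"))
  jsonlite::write_json(
    list(image_shape = scene$image_shape,
         pixel_size_um = scene$pixel_size_um),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read scene ground truth written by [write_scene_truth()]
#'
#' @param dir Directory written by [write_scene_truth()].
#' @return A list with tibbles `components`, `puncta`, `pla`, `cells`,
#'   integer matrices `cell_labels` and `mito_mask`, `image_shape` and
#'   `pixel_size_um`.
#' @export
read_scene_truth <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  list(
    components = readr::read_csv(file.path(dir, "components.csv"),
                                 show_col_types = FALSE),
    puncta = readr::read_csv(file.path(dir, "puncta.csv"),
                             show_col_types = FALSE),
    pla = readr::read_csv(file.path(dir, "pla.csv"), show_col_types = FALSE),
    cells = readr::read_csv(file.path(dir, "cells.csv"),
                            show_col_types = FALSE),
    cell_labels = read_label_tiff(file.path(dir, "cell_labels.tif")),
    mito_mask = read_label_tiff(file.path(dir, "mito_mask.tif")),
    image_shape = meta$image_shape,
    pixel_size_um = meta$pixel_size_um
  )
}
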