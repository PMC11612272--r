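#' Write / read a tissue label map as PNG + legend JSON
#'
#' The raster is stored as a single-channel 8-bit lossless PNG (class codes
#' as gray levels) with the class legend in a sidecar JSON object
#' `{class_name: code}`. `mpp` is not part of the raster format and is
#' supplied on read.
#'
#' @param map A [label_map()].
#' @param path PNG path.
#' @param legend_path Sidecar JSON path; default `<path>.legend.json`.
#' @return `write_label_map` invisibly returns `path`; `read_label_map`
#'   returns a [label_map()].
#' @export
write_label_map <- function(map, path, legend_path = paste0(path, ".legend.json")) {
  stopifnot(inherits(map, "label_map"))
  if (max(map) > 255L) stop("class codes exceed 8-bit range", call. = FALSE)
  png::writePNG(unclass(map) / 255, path)
  legend <- map_legend(map)
  jsonlite::write_json(as.list(legend), legend_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_map
#' @param mpp Microns per pixel of the stored raster.
#' @export
read_label_map <- function(path, legend_path = paste0(path, ".legend.json"),
                           mpp = 0.25) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) {
      stop("multi-channel raster: label maps must be single-channel",
           call. = FALSE)
    }
    img <- img[, , 1L]
  }
  mat <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  legend_raw <- jsonlite::read_json(legend_path)
  legend <- stats::setNames(as.integer(unlist(legend_raw)), names(legend_raw))
  validate_legend(legend)
  bad <- setdiff(unique(as.vector(mat)), as.integer(legend))
  if (length(bad)) {
    stop("raster contains code(s) absent from legend: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  label_map(mat, legend, mpp)
}

#' Write / read an artifact mask as a 0/1 PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `write_artifact_mask` invisibly returns `path`;
#'   `read_artifact_mask` returns a logical matrix.
#' @export
write_artifact_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_artifact_mask
#' @export
read_artifact_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(img > 0.5, nrow(img), ncol(img))
}

#' Write / read a cell point set as CSV
#'
#' CSV with header `cell_id,x_um,y_um,cell_class`, comma-separated, UTF-8,
#' `.` decimal, missing = empty field. Reading validates classes against
#' [cell_legend()], coordinate finiteness, and `cell_id` uniqueness.
#'
#' @param cells Cell set tibble.
#' @param path CSV path.
#' @return `write_cells` invisibly returns `path`; `read_cells` a tibble.
#' @export
write_cells <- function(cells, path) {
  readr::write_csv(validate_cell_set(cells)[, c("cell_id", "x_um", "y_um",
                                                "cell_class")], path)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          cell_id = readr::col_character(),
                          x_um = readr::col_character(),
                          y_um = readr::col_character(),
                          cell_class = readr::col_character()
                        ))
  req <- c("cell_id", "x_um", "y_um", "cell_class")
  if (!all(req %in% names(df))) {
    stop("cells CSV must have header ", paste(req, collapse = ","),
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(df$x_um))
  y <- suppressWarnings(as.numeric(df$y_um))
  bad_num <- which(!is.finite(x) | !is.finite(y))
  if (length(bad_num)) {
    stop("non-numeric coordinate at row ", bad_num[1], call. = FALSE)
  }
  bad_cls <- which(!df$cell_class %in% names(cell_legend()))
  if (length(bad_cls)) {
    stop("unknown cell class '", df$cell_class[bad_cls[1]], "' at row ",
         bad_cls[1], call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id at row ", which(duplicated(df$cell_id))[1],
         call. = FALSE)
  }
  cell_set(df$cell_id, x, y, df$cell_class)
}

#' Write / read cells as a GeoJSON point collection
#'
#' Each cell becomes a Point feature (coordinates in microns) with
#' `cell_id` and `cell_class` properties.
#'
#' @param cells Cell set tibble.
#' @param path GeoJSON path.
#' @return `write_cells_geojson` invisibly returns `path`;
#'   `read_cells_geojson` a tibble.
#' @export
write_cells_geojson <- function(cells, path) {
  cells <- validate_cell_set(cells)
  features <- purrr::pmap(cells, function(cell_id, x_um, y_um, cell_class) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(x_um, y_um)),
      properties = list(cell_id = cell_id, cell_class = cell_class)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_cells_geojson
#' @export
read_cells_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  rows <- purrr::map(feats, function(f) {
    tibble::tibble(
      cell_id = f$properties$cell_id,
      x_um = as.numeric(f$geometry$coordinates[[1]]),
      y_um = as.numeric(f$geometry$coordinates[[2]]),
      cell_class = f$properties$cell_class
    )
  })
  validate_cell_set(dplyr::bind_rows(rows, cell_set()))
}

#' Write / read cohort metadata CSV (`slide_id,grade,group`)
#'
#' @param metadata Tibble with `slide_id`, `grade`, `group`.
#' @param path CSV path.
#' @return `write_metadata` invisibly returns `path`; `read_metadata` a
#'   tibble.
#' @export
write_metadata <- function(metadata, path) {
  stopifnot(all(c("slide_id", "grade", "group") %in% names(metadata)))
  readr::write_csv(metadata[, c("slide_id", "grade", "group")], path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Write a whole slide bundle into a directory
#'
#' Writes `<slide_id>.png` (+ legend JSON), `<slide_id>.cells.csv` and
#' `<slide_id>.mask.png` under `dir`.
#'
#' @param bundle A [slide_bundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_slide_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, bundle$slide_id)
  paths <- c(
    label_map = paste0(base, ".png"),
    legend = paste0(base, ".png.legend.json"),
    cells = paste0(base, ".cells.csv"),
    mask = paste0(base, ".mask.png")
  )
  write_label_map(bundle$label_map, paths[["label_map"]], paths[["legend"]])
  write_cells(bundle$cells, paths[["cells"]])
  write_artifact_mask(bundle$artifact_mask, paths[["mask"]])
  invisible(paths)
}

#' @rdname write_slide_bundle
#' @param slide_id Slide id (file stem) to read back.
#' @param grade Marsh grade to record in the bundle.
#' @param mpp Microns per pixel.
#' @export
read_slide_bundle <- function(dir, slide_id, grade = NA_character_,
                              mpp = 0.25) {
  base <- file.path(dir, slide_id)
  map <- read_label_map(paste0(base, ".png"),
                        paste0(base, ".png.legend.json"), mpp = mpp)
  cells <- read_cells(paste0(base, ".cells.csv"))
  mask_path <- paste0(base, ".mask.png")
  mask <- if (file.exists(mask_path)) read_artifact_mask(mask_path) else NULL
  slide_bundle(map, cells, mask, grade = grade, slide_id = slide_id)
}
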