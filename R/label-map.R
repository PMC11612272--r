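#' Construct a tissue label map
#'
#' A label map is a single-channel integer raster assigning every pixel one
#' tissue class, together with its class legend and physical scale. It is the
#' geometric substrate of all area features. Coordinates follow image
#' convention: origin at the top-left corner, x along columns, y along rows,
#' both in microns; pixel `(row i, col j)` (0-based) covers
#' `x in [j*mpp, (j+1)*mpp)` and `y in [i*mpp, (i+1)*mpp)`.
#'
#' @param mat Integer matrix of class codes (rows = y, columns = x).
#' @param legend Named integer vector, class name -> code (see
#'   [tissue_legend()]). Every pixel value must appear in the legend.
#' @param mpp Microns per pixel; must be positive.
#' @return A `label_map` object (integer matrix with `legend` and `mpp`
#'   attributes).
#' @export
label_map <- function(mat, legend = tissue_legend(), mpp = 0.25) {
  if (!is.matrix(mat)) stop("`mat` must be a matrix", call. = FALSE)
  storage.mode(mat) <- "integer"
  validate_legend(legend)
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0) {
    stop("`mpp` must be a single positive number", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(mat)), as.integer(legend))
  if (length(bad)) {
    stop("pixel code(s) not in legend: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(mat, legend = legend, mpp = as.numeric(mpp), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  legend <- attr(x, "legend")
  counts <- class_pixel_counts(x)
  cat(sprintf("<label_map> %d x %d px, mpp = %g um/px\n", nrow(x), ncol(x),
              attr(x, "mpp")))
  shown <- counts[counts > 0]
  cat("  classes:",
      paste(sprintf("%s=%d", names(shown), shown), collapse = ", "), "\n")
  invisible(x)
}

map_legend <- function(map) attr(map, "legend")
map_mpp    <- function(map) attr(map, "mpp")

#' Per-class pixel counts of a label map
#'
#' @param map A [label_map()].
#' @return Named integer vector, one entry per legend class (zero where the
#'   class is absent). Counts always sum to the raster size.
#' @export
class_pixel_counts <- function(map) {
  legend <- map_legend(map)
  tab <- tabulate(as.vector(map) + 1L, nbins = max(legend) + 1L)
  stats::setNames(tab[as.integer(legend) + 1L], names(legend))
}

# area of one pixel in mm^2
pixel_area_mm2 <- function(map) (map_mpp(map)^2) * 1e-6

#' Construct a cell point set
#'
#' @param cell_id Character or integer ids, unique.
#' @param x_um,y_um Positions in microns (image convention, origin top-left).
#' @param cell_class Character, values from [cell_legend()] names.
#' @return A tibble with columns `cell_id`, `x_um`, `y_um`, `cell_class`.
#' @export
cell_set <- function(cell_id = character(), x_um = numeric(),
                     y_um = numeric(), cell_class = character()) {
  out <- tibble::tibble(
    cell_id = as.character(cell_id),
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um),
    cell_class = as.character(cell_class)
  )
  validate_cell_set(out)
}

validate_cell_set <- function(cells) {
  req <- c("cell_id", "x_um", "y_um", "cell_class")
  if (!all(req %in% names(cells))) {
    stop("cell set must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells)) {
    if (anyDuplicated(cells$cell_id)) {
      stop("duplicate cell_id in cell set", call. = FALSE)
    }
    bad <- !cells$cell_class %in% names(cell_legend())
    if (any(bad)) {
      stop("unknown cell class at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "), ": ",
           paste(utils::head(unique(cells$cell_class[bad]), 3L), collapse = ", "),
           call. = FALSE)
    }
    if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
      stop("cell coordinates must be finite", call. = FALSE)
    }
  }
  cells
}

#' Bundle one slide's inputs
#'
#' A slide bundle holds everything the feature extractor needs for one slide:
#' the tissue label map, the classified cell point set, an artifact mask
#' (TRUE where tissue quality is too poor to quantify), and the slide's
#' modified Marsh grade.
#'
#' @param label_map A [label_map()].
#' @param cells A cell set tibble (see [cell_set()]).
#' @param artifact_mask Logical matrix, same shape as `label_map`; defaults
#'   to all-FALSE.
#' @param grade Modified Marsh grade, one of [marsh_levels()], or `NA`.
#' @param slide_id Slide identifier string.
#' @return A `slide_bundle` list.
#' @export
slide_bundle <- function(label_map, cells = cell_set(), artifact_mask = NULL,
                         grade = NA_character_, slide_id = "slide") {
  stopifnot(inherits(label_map, "label_map"))
  if (is.null(artifact_mask)) {
    artifact_mask <- matrix(FALSE, nrow(label_map), ncol(label_map))
  }
  if (!is.logical(artifact_mask) || !identical(dim(artifact_mask), dim(label_map))) {
    stop("artifact_mask must be a logical matrix with the label map's shape",
         call. = FALSE)
  }
  cells <- validate_cell_set(cells)
  if (nrow(cells)) {
    mpp <- map_mpp(label_map)
    w_um <- ncol(label_map) * mpp
    h_um <- nrow(label_map) * mpp
    oob <- cells$x_um < 0 | cells$x_um >= w_um | cells$y_um < 0 | cells$y_um >= h_um
    if (any(oob)) {
      stop(sum(oob), " cell(s) outside the raster bounds", call. = FALSE)
    }
  }
  if (!is.na(grade) && !grade %in% marsh_levels()) {
    stop("unknown Marsh grade: ", grade, call. = FALSE)
  }
  structure(
    list(label_map = label_map, cells = cells, artifact_mask = artifact_mask,
         grade = grade, slide_id = slide_id),
    class = "slide_bundle"
  )
}

#' @export
print.slide_bundle <- function(x, ...) {
  cat(sprintf("<slide_bundle> %s: grade %s, %d x %d px, %d cells, %.1f%% artifact\n",
              x$slide_id, x$grade, nrow(x$label_map), ncol(x$label_map),
              nrow(x$cells), 100 * mean(x$artifact_mask)))
  invisible(x)
}
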