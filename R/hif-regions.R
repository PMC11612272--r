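#' Tissue compartment definitions
#'
#' Compartments are named sets of tissue classes. Beyond the atomic classes,
#' three derived compartments are fixed: `all_epithelium` (villous + crypt
#' epithelium, excluding lumen), `mucosa` (both epithelia, crypt lumen,
#' lamina propria, muscularis mucosae), and `usable_tissue` (every
#' non-background class except artifact -- i.e. all tissue that survives
#' artifact exclusion).
#'
#' @return Named list of character vectors of member tissue classes.
#' @export
tissue_compartments <- function() {
  atoms <- setdiff(names(tissue_legend()), c("background", "artifact"))
  c(
    stats::setNames(lapply(atoms, identity), atoms),
    list(
      all_epithelium = c("villous_epithelium", "crypt_epithelium"),
      mucosa = c("villous_epithelium", "crypt_epithelium", "crypt_lumen",
                 "lamina_propria", "muscularis_mucosa"),
      usable_tissue = atoms
    )
  )
}

resolve_compartment <- function(map, compartment) {
  legend <- map_legend(map)
  members <- if (is.character(compartment) && length(compartment) == 1L &&
                 compartment %in% names(tissue_compartments())) {
    tissue_compartments()[[compartment]]
  } else {
    as.character(compartment)
  }
  bad <- setdiff(members, names(legend))
  if (length(bad)) {
    stop("compartment member(s) not in legend: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(legend[members])
}

#' Recode artifact-masked pixels
#'
#' Pixels under the mask are recoded to the `artifact` class; all other
#' pixels are unchanged. Because every area and cell feature ignores the
#' artifact class, this removes low-quality regions (debris, folds,
#' out-of-focus) from quantification.
#'
#' @param map A [label_map()].
#' @param artifact_mask Logical matrix, same shape as `map`.
#' @return A new [label_map()].
#' @export
apply_artifact_exclusion <- function(map, artifact_mask) {
  if (!identical(dim(artifact_mask), dim(map))) {
    stop("artifact mask shape ", paste(dim(artifact_mask), collapse = "x"),
         " does not match label map ", paste(dim(map), collapse = "x"),
         call. = FALSE)
  }
  out <- unclass(map)
  out[artifact_mask] <- map_legend(map)[["artifact"]]
  label_map(out, map_legend(map), map_mpp(map))
}

#' Compartment area in mm^2
#'
#' Pixel count of the compartment's member classes times the pixel area
#' (`mpp^2 * 1e-6` mm^2). Artifact-recoded pixels are never counted.
#'
#' @param map A [label_map()].
#' @param compartment A compartment name from [tissue_compartments()] or a
#'   character vector of tissue classes.
#' @return Area in mm^2.
#' @export
region_area <- function(map, compartment) {
  codes <- resolve_compartment(map, compartment)
  sum(as.vector(map) %in% codes) * pixel_area_mm2(map)
}

#' Area proportion of one compartment over another
#'
#' Unitless ratio of [region_area()] values (the pixel scale cancels). A
#' zero-area denominator yields `NA` -- an undefined feature, never 0.
#'
#' @param map A [label_map()].
#' @param numerator,denominator Compartment names or class vectors.
#' @return Ratio, or `NA_real_` when the denominator has zero area.
#' @export
area_proportion <- function(map, numerator, denominator) {
  num <- sum(as.vector(map) %in% resolve_compartment(map, numerator))
  den <- sum(as.vector(map) %in% resolve_compartment(map, denominator))
  if (den == 0L) return(NA_real_)
  num / den
}

#' Restrict a cell set to a tissue compartment
#'
#' A cell belongs to the pixel containing it: 0-based
#' `floor(coordinate / mpp)` with origin at the top-left and half-open
#' pixel cells. Cells outside the raster are excluded with a warning.
#'
#' @param cells Cell set tibble.
#' @param map A [label_map()].
#' @param compartment Compartment name or class vector.
#' @return The subset of `cells` lying on compartment pixels.
#' @export
cells_in_region <- function(cells, map, compartment) {
  cells <- validate_cell_set(cells)
  if (!nrow(cells)) return(cells)
  codes <- resolve_compartment(map, compartment)
  mpp <- map_mpp(map)
  col0 <- floor(cells$x_um / mpp)
  row0 <- floor(cells$y_um / mpp)
  inb <- col0 >= 0 & col0 < ncol(map) & row0 >= 0 & row0 < nrow(map)
  if (any(!inb)) {
    warning(sum(!inb), " cell(s) outside raster bounds excluded",
            call. = FALSE)
  }
  pix <- rep(NA_integer_, nrow(cells))
  pix[inb] <- map[cbind(row0[inb] + 1L, col0[inb] + 1L)]
  cells[!is.na(pix) & pix %in% codes, , drop = FALSE]
}

#' Cell density in a compartment
#'
#' Count of cells of `cell_class` on compartment pixels divided by the
#' compartment area in mm^2. Zero-area compartments yield `NA`.
#'
#' @param cells Cell set tibble.
#' @param cell_class A cell class name, or `"all"` for every class.
#' @param map A [label_map()].
#' @param compartment Compartment name or class vector.
#' @return Density in cells/mm^2, or `NA_real_`.
#' @export
cell_density <- function(cells, cell_class, map, compartment) {
  area <- region_area(map, compartment)
  if (area == 0) return(NA_real_)
  inside <- cells_in_region(cells, map, compartment)
  n <- if (identical(cell_class, "all")) nrow(inside) else {
    sum(inside$cell_class %in% cell_class)
  }
  n / area
}

#' Count proportion of one cell class over others in a compartment
#'
#' Count of numerator-class cells divided by the count of
#' denominator-class cells, both restricted to the compartment.
#' `denominator_classes = "all"` means every cell class. A zero
#' denominator count yields `NA`.
#'
#' @param cells Cell set tibble.
#' @param numerator_class Cell class name.
#' @param denominator_classes Character vector of classes, or `"all"`.
#' @param map A [label_map()].
#' @param compartment Compartment name or class vector.
#' @return Ratio, or `NA_real_`.
#' @export
count_proportion <- function(cells, numerator_class, denominator_classes,
                             map, compartment) {
  inside <- cells_in_region(cells, map, compartment)
  den <- if (identical(denominator_classes, "all")) nrow(inside) else {
    sum(inside$cell_class %in% denominator_classes)
  }
  if (den == 0L) return(NA_real_)
  sum(inside$cell_class %in% numerator_class) / den
}
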