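#' Tissue class legend
#'
#' The fixed taxonomy of duodenal tissue compartments used throughout the
#' package: villous and crypt epithelium, crypt lumen, lamina propria, blood
#' vessels, muscularis mucosae, a generic other-tissue class (Brunner's
#' glands, submucosa), plus `background` (always code 0) and an `artifact`
#' class that artifact exclusion recodes low-quality pixels to.
#'
#' @return Named integer vector mapping class name to raster code.
#' @export
#' @examples
#' tissue_legend()
tissue_legend <- function() {
  c(
    background          = 0L,
    villous_epithelium  = 1L,
    crypt_epithelium    = 2L,
    crypt_lumen         = 3L,
    lamina_propria      = 4L,
    blood_vessel        = 5L,
    muscularis_mucosa   = 6L,
    other_tissue        = 7L,
    artifact            = 8L
  )
}

#' Cell class legend
#'
#' The fixed set of cell classes called on H&E duodenal biopsies:
#' granulocytes, plasma cells, enterocytes, intraepithelial and
#' non-intraepithelial lymphocytes, eosinophils, goblet cells, and a
#' catch-all other-cell class.
#'
#' @return Named integer vector mapping cell class name to code.
#' @export
cell_legend <- function() {
  c(
    neutrophil                 = 1L,
    plasma_cell                = 2L,
    enterocyte                 = 3L,
    intraepithelial_lymphocyte = 4L,
    lymphocyte                 = 5L,
    eosinophil                 = 6L,
    goblet_cell                = 7L,
    other_cell                 = 8L
  )
}

#' Modified Marsh grade levels
#'
#' Ordered levels of the modified Marsh (Marsh-Oberhuber) score: 0 normal,
#' 1 infiltrative, 2 hyperplastic, 3a/3b/3c destructive lesions.
#'
#' @return Character vector of the six grade labels in severity order.
#' @export
marsh_levels <- function() c("0", "1", "2", "3a", "3b", "3c")

validate_legend <- function(legend, require_background = TRUE) {
  if (is.null(names(legend)) || any(!nzchar(names(legend)))) {
    stop("legend must be a named vector of class codes", call. = FALSE)
  }
  codes <- as.integer(legend)
  if (anyDuplicated(codes)) stop("legend codes must be unique", call. = FALSE)
  if (any(codes < 0)) stop("legend codes must be non-negative", call. = FALSE)
  if (require_background) {
    if (!"background" %in% names(legend) || legend[["background"]] != 0L) {
      stop("legend must map 'background' to code 0", call. = FALSE)
    }
  }
  invisible(legend)
}
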