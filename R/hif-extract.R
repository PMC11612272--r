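#' Names of the 18 core HIFs (and 2 extended IEL features)
#'
#' The verbatim feature names of the human-interpretable feature catalogue:
#' villous-atrophy area proportions, crypt-hyperplasia area proportions, the
#' villous/crypt surrogate for the villous-height/crypt-depth ratio,
#' intraepithelial-lymphocyte infiltration features, lamina-propria
#' inflammation features, and mucosa-wide granulocyte count proportions.
#'
#' @param extended Also return the two extended crypt-IEL features.
#' @return Character vector of feature names, in canonical report order.
#' @export
hif_feature_names <- function(extended = FALSE) {
  core <- c(
    "Area proportion of villous epithelium over mucosa in tissue",
    "Area proportion of villous epithelium over all epithelium in tissue",
    "Area proportion of villous epithelium over lamina propria in tissue",
    "Area proportion of crypt epithelium over usable tissue",
    "Area proportion of lamina propria over crypt epithelium in tissue",
    "Area proportion of crypt epithelium over all epithelium in tissue",
    "Area proportion of crypt epithelium over mucosa in tissue",
    "Area proportion of villous epithelium over crypt epithelium in tissue",
    "Count proportion of intraepithelial lymphocytes over enterocytes in villous epithelium",
    "Density of intraepithelial lymphocytes in villous epithelium",
    "Count proportion of plasma cells over all cells in lamina propria",
    "Density of plasma cells in lamina propria",
    "Density of lymphocytes in lamina propria",
    "Count proportion of lymphocytes over all cells in lamina propria",
    "Area proportion of lamina propria over mucosa in tissue",
    "Total number of cells in lamina propria",
    "Count proportion of neutrophils over all cells in mucosa",
    "Count proportion of eosinophils over all cells in mucosa"
  )
  if (!extended) return(core)
  c(core,
    "Density of intraepithelial lymphocytes in crypt epithelium",
    "Density ratio of intraepithelial lymphocytes villous to crypt epithelium")
}

#' Extract the HIF catalogue from one slide
#'
#' Applies artifact exclusion to the bundle's label map, then computes all
#' 18 core features (plus the two extended crypt-IEL features when
#' requested). Undefined ratios (zero-area or zero-count denominators) are
#' recorded as `NA`, never 0, and are excluded pairwise from downstream
#' statistics. A pure function of the bundle.
#'
#' @param bundle A [slide_bundle()].
#' @param extended Include the extended crypt-IEL features (default TRUE).
#' @return One-row tibble: `slide_id` plus one column per feature name.
#' @export
#' @examples
#' b <- simulate_slide("0", shape = c(96, 96), seed = 1)
#' extract_hifs(b)[["Area proportion of villous epithelium over mucosa in tissue"]]
extract_hifs <- function(bundle, extended = TRUE) {
  stopifnot(inherits(bundle, "slide_bundle"))
  map <- apply_artifact_exclusion(bundle$label_map, bundle$artifact_mask)
  cells <- bundle$cells

  dens_iel_v <- cell_density(cells, "intraepithelial_lymphocyte", map,
                             "villous_epithelium")
  dens_iel_c <- cell_density(cells, "intraepithelial_lymphocyte", map,
                             "crypt_epithelium")
  lp_cells <- cells_in_region(cells, map, "lamina_propria")

  vals <- c(
    area_proportion(map, "villous_epithelium", "mucosa"),
    area_proportion(map, "villous_epithelium", "all_epithelium"),
    area_proportion(map, "villous_epithelium", "lamina_propria"),
    area_proportion(map, "crypt_epithelium", "usable_tissue"),
    area_proportion(map, "lamina_propria", "crypt_epithelium"),
    area_proportion(map, "crypt_epithelium", "all_epithelium"),
    area_proportion(map, "crypt_epithelium", "mucosa"),
    area_proportion(map, "villous_epithelium", "crypt_epithelium"),
    count_proportion(cells, "intraepithelial_lymphocyte", "enterocyte",
                     map, "villous_epithelium"),
    dens_iel_v,
    count_proportion(cells, "plasma_cell", "all", map, "lamina_propria"),
    cell_density(cells, "plasma_cell", map, "lamina_propria"),
    cell_density(cells, "lymphocyte", map, "lamina_propria"),
    count_proportion(cells, "lymphocyte", "all", map, "lamina_propria"),
    area_proportion(map, "lamina_propria", "mucosa"),
    as.numeric(nrow(lp_cells)),
    count_proportion(cells, "neutrophil", "all", map, "mucosa"),
    count_proportion(cells, "eosinophil", "all", map, "mucosa")
  )
  nms <- hif_feature_names(extended = extended)
  if (extended) {
    ratio_vc <- if (is.na(dens_iel_v) || is.na(dens_iel_c) || dens_iel_c == 0) {
      NA_real_
    } else dens_iel_v / dens_iel_c
    vals <- c(vals, dens_iel_c, ratio_vc)
  }
  out <- tibble::as_tibble(stats::setNames(as.list(vals), nms))
  dplyr::bind_cols(tibble::tibble(slide_id = bundle$slide_id), out)
}

#' Extract HIFs for a whole cohort
#'
#' @param cohort A list with `slides` (list of bundles), as returned by
#'   [simulate_cohort()], or a bare list of bundles.
#' @param extended Include extended crypt-IEL features.
#' @return Tibble, one row per slide.
#' @export
extract_cohort_hifs <- function(cohort, extended = TRUE) {
  slides <- if (!is.null(cohort$slides)) cohort$slides else cohort
  dplyr::bind_rows(purrr::map(slides, extract_hifs, extended = extended))
}

#' Intraepithelial lymphocytosis flag
#'
#' A defining feature of celiac disease is the presence of more than 30
#' intraepithelial lymphocytes per 100 enterocytes in the duodenum. The
#' flag is TRUE iff the IEL-per-enterocyte count proportion strictly
#' exceeds 0.30; an undefined proportion gives `NA`.
#'
#' @param x Numeric IEL/enterocyte count proportion(s), or a HIF tibble
#'   from [extract_hifs()] (the proportion column is used).
#' @return Logical vector.
#' @export
#' @examples
#' iel_flag(c(0.20, 0.30, 0.31))
iel_flag <- function(x) {
  if (is.data.frame(x)) {
    col <- "Count proportion of intraepithelial lymphocytes over enterocytes in villous epithelium"
    if (!col %in% names(x)) stop("HIF table lacks the IEL/enterocyte column",
                                 call. = FALSE)
    x <- x[[col]]
  }
  x > 30 / 100
}
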