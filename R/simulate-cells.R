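#' Populate a label map with classified cells
#'
#' Places cells by a homogeneous Poisson point process within each tissue
#' compartment, at per-slide densities drawn from the grade targets, then
#' enforces a minimum inter-cell spacing by thinning. Intraepithelial
#' lymphocytes are placed only in epithelial compartments. Villous
#' enterocyte density is derived per slide as the drawn IEL density divided
#' by the drawn IEL-per-enterocyte ratio, so both the density and the count
#' proportion calibrate to their targets; lamina-propria plasma cells and
#' lymphocytes are drawn as count proportions of a drawn total density for
#' the same reason.
#'
#' @param label_map A [label_map()].
#' @param params A [grade_params()] object.
#' @param seed Integer seed; deterministic given seed.
#' @param min_spacing_um Minimum inter-cell spacing enforced by thinning
#'   (default 3 um, about a nuclear radius).
#' @return A cell set tibble ([cell_set()]).
#' @export
populate_cells <- function(label_map, params, seed = 1L, min_spacing_um = 3) {
  validate_grade_params(params)
  legend <- map_legend(label_map)
  mpp <- map_mpp(label_map)

  withr::with_seed(seed, {
    # per-slide density draws, cells/mm^2
    d_iel_v <- rnorm_clamped(1, params$iel_density_villous)
    ratio   <- rnorm_clamped(1, params$iel_per_enterocyte, 0.02, 2)
    d_ent_v <- d_iel_v / ratio
    d_gob_v <- rnorm_clamped(1, params$goblet_density_villous)
    d_oth_e <- rnorm_clamped(1, params$other_density_epith)

    d_ent_c <- rnorm_clamped(1, params$enterocyte_density_crypt)
    d_iel_c <- rnorm_clamped(1, params$iel_density_crypt)
    d_gob_c <- rnorm_clamped(1, params$goblet_density_crypt)

    d_lp_tot <- rnorm_clamped(1, params$lp_total_density)
    p_plasma <- rnorm_clamped(1, params$plasma_prop_lp, 0, 1)
    p_lymph  <- rnorm_clamped(1, params$lymph_prop_lp, 0, 1)
    d_neut   <- rnorm_clamped(1, params$neut_density_lp)
    d_eos    <- rnorm_clamped(1, params$eos_density_lp)
    d_plasma <- d_lp_tot * p_plasma
    d_lymph  <- d_lp_tot * p_lymph
    d_oth_lp <- max(0, d_lp_tot - d_plasma - d_lymph - d_neut - d_eos)

    plan <- tibble::tribble(
      ~compartment,         ~cell_class,                  ~density,
      "villous_epithelium", "enterocyte",                 d_ent_v,
      "villous_epithelium", "intraepithelial_lymphocyte", d_iel_v,
      "villous_epithelium", "goblet_cell",                d_gob_v,
      "villous_epithelium", "other_cell",                 d_oth_e,
      "crypt_epithelium",   "enterocyte",                 d_ent_c,
      "crypt_epithelium",   "intraepithelial_lymphocyte", d_iel_c,
      "crypt_epithelium",   "goblet_cell",                d_gob_c,
      "crypt_epithelium",   "other_cell",                 d_oth_e,
      "lamina_propria",     "plasma_cell",                d_plasma,
      "lamina_propria",     "lymphocyte",                 d_lymph,
      "lamina_propria",     "neutrophil",                 d_neut,
      "lamina_propria",     "eosinophil",                 d_eos,
      "lamina_propria",     "other_cell",                 d_oth_lp
    )

    px_mm2 <- pixel_area_mm2(label_map)
    pts <- purrr::pmap(plan, function(compartment, cell_class, density) {
      if (density <= 0) return(NULL)
      idx <- which(label_map == legend[[compartment]])
      if (!length(idx)) {
        warning("compartment '", compartment, "' has zero area; skipping ",
                cell_class, call. = FALSE)
        return(NULL)
      }
      n <- stats::rpois(1, density * length(idx) * px_mm2)
      if (n == 0L) return(NULL)
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      H <- nrow(label_map)
      row0 <- (pick - 1L) %% H          # 0-based
      col0 <- (pick - 1L) %/% H
      tibble::tibble(
        x_um = (col0 + stats::runif(n)) * mpp,
        y_um = (row0 + stats::runif(n)) * mpp,
        cell_class = cell_class
      )
    })
    cells <- dplyr::bind_rows(pts)
    if (!nrow(cells)) return(cell_set())
    if (nrow(cells)) {
      keep <- thin_points(cells$x_um, cells$y_um,
                          sample.int(nrow(cells)), min_spacing_um)
      cells <- cells[keep, , drop = FALSE]
    }
    cell_set(
      cell_id = sprintf("c%06d", seq_len(nrow(cells))),
      x_um = cells$x_um, y_um = cells$y_um, cell_class = cells$cell_class
    )
  })
}

# Sequential thinning in the given order: keep a point iff no already-kept
# point lies within `spacing`. Grid-hashed so it stays O(n).
thin_points <- function(x, y, order, spacing) {
  if (spacing <= 0) return(sort(order))
  gx <- floor(x / spacing); gy <- floor(y / spacing)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(length(x))
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  for (i in order) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      key <- paste0(gx[i] + offs$dx[k], ",", gy[i] + offs$dy[k])
      js <- seen[[key]]
      if (!is.null(js) &&
          any((x[js] - x[i])^2 + (y[js] - y[i])^2 < spacing^2)) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      key <- paste0(gx[i], ",", gy[i])
      seen[[key]] <- c(seen[[key]], i)
    }
  }
  which(keep)
}
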