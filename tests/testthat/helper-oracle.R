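# Independent brute-force recomputation of every HIF by explicit per-pixel
# and per-cell loops. Deliberately shares no code with the package
# implementation beyond the legends.

oracle_hifs <- function(bundle, extended = TRUE) {
  legend <- tissue_legend()
  cl_names <- names(legend)
  map <- bundle$label_map
  mpp <- attr(map, "mpp")
  H <- nrow(map); W <- ncol(map)

  # artifact exclusion, pixel by pixel
  m <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    m[i, j] <- if (bundle$artifact_mask[i, j]) legend[["artifact"]] else map[i, j]
  }

  # per-class pixel counts
  px <- stats::setNames(rep(0L, length(legend)), cl_names)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    nm <- cl_names[match(m[i, j], legend)]
    px[nm] <- px[nm] + 1L
  }

  comp <- list(
    villous = "villous_epithelium",
    crypt = "crypt_epithelium",
    lumen = "crypt_lumen",
    lp = "lamina_propria",
    mm = "muscularis_mucosa",
    epith = c("villous_epithelium", "crypt_epithelium"),
    mucosa = c("villous_epithelium", "crypt_epithelium", "crypt_lumen",
               "lamina_propria", "muscularis_mucosa"),
    usable = c("villous_epithelium", "crypt_epithelium", "crypt_lumen",
               "lamina_propria", "blood_vessel", "muscularis_mucosa",
               "other_tissue")
  )
  cnt <- function(k) sum(px[comp[[k]]])
  area <- function(k) cnt(k) * mpp^2 * 1e-6
  aprop <- function(a, b) if (cnt(b) == 0) NA_real_ else cnt(a) / cnt(b)

  # per-cell compartment membership
  cells <- bundle$cells
  in_comp <- function(k) {
    keep <- logical(nrow(cells))
    for (r in seq_len(nrow(cells))) {
      cx <- floor(cells$x_um[r] / mpp) + 1
      cy <- floor(cells$y_um[r] / mpp) + 1
      if (cx >= 1 && cx <= W && cy >= 1 && cy <= H) {
        nm <- cl_names[match(m[cy, cx], legend)]
        keep[r] <- nm %in% comp[[k]]
      }
    }
    cells[keep, , drop = FALSE]
  }
  ncls <- function(df, cl) sum(df$cell_class == cl)
  dens <- function(cl, k) if (area(k) == 0) NA_real_ else ncls(in_comp(k), cl) / area(k)
  cprop <- function(cl, den_cl, k) {
    df <- in_comp(k)
    d <- if (identical(den_cl, "all")) nrow(df) else ncls(df, den_cl)
    if (d == 0) NA_real_ else ncls(df, cl) / d
  }

  out <- c(
    aprop("villous", "mucosa"),
    aprop("villous", "epith"),
    aprop("villous", "lp"),
    aprop("crypt", "usable"),
    aprop("lp", "crypt"),
    aprop("crypt", "epith"),
    aprop("crypt", "mucosa"),
    aprop("villous", "crypt"),
    cprop("intraepithelial_lymphocyte", "enterocyte", "villous"),
    dens("intraepithelial_lymphocyte", "villous"),
    cprop("plasma_cell", "all", "lp"),
    dens("plasma_cell", "lp"),
    dens("lymphocyte", "lp"),
    cprop("lymphocyte", "all", "lp"),
    aprop("lp", "mucosa"),
    as.numeric(nrow(in_comp("lp"))),
    cprop("neutrophil", "all", "mucosa"),
    cprop("eosinophil", "all", "mucosa")
  )
  if (extended) {
    dv <- dens("intraepithelial_lymphocyte", "villous")
    dc <- dens("intraepithelial_lymphocyte", "crypt")
    ratio <- if (is.na(dv) || is.na(dc) || dc == 0) NA_real_ else dv / dc
    out <- c(out, dc, ratio)
  }
  stats::setNames(out, hif_feature_names(extended = extended))
}
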