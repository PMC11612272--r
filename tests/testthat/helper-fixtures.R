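# Fixture builders shared across test files. Everything is generated in
# code at test time; no data files.

# a random small bundle (raster up to 32 x 32) for oracle-equivalence and
# property tests; not produced by the generator, which requires >= 64 px
random_tiny_bundle <- function(seed) {
  withr::with_seed(seed, {
    H <- sample(8:32, 1)
    W <- sample(8:32, 1)
    mpp <- sample(c(0.5, 1, 2), 1)
    legend <- tissue_legend()
    codes <- unname(legend[setdiff(names(legend), "artifact")])
    mat <- matrix(sample(codes, H * W, replace = TRUE), H, W)
    mask <- matrix(stats::runif(H * W) < 0.1, H, W)
    n <- sample(0:40, 1)
    cells <- cell_set(
      cell_id = sprintf("c%03d", seq_len(n)),
      x_um = stats::runif(n, 0, W * mpp),
      y_um = stats::runif(n, 0, H * mpp),
      cell_class = sample(names(cell_legend()), n, replace = TRUE)
    )
    slide_bundle(label_map(mat, legend, mpp), cells, mask,
                 grade = sample(marsh_levels(), 1),
                 slide_id = paste0("tiny", seed))
  })
}

# a deterministic hand-countable 20 x 20 bundle (mpp = 1 so px = um^2)
hand_built_bundle <- function() {
  legend <- tissue_legend()
  mat <- matrix(legend[["background"]], 20, 20)
  mat[3:8, ]   <- legend[["villous_epithelium"]]   # 120 px
  mat[9:12, ]  <- legend[["lamina_propria"]]       # 80 px
  mat[13:15, ] <- legend[["crypt_epithelium"]]     # 60 px
  mat[16, ]    <- legend[["crypt_lumen"]]          # 20 px
  mat[17, ]    <- legend[["muscularis_mucosa"]]    # 20 px
  mat[18, ]    <- legend[["other_tissue"]]         # 20 px
  map <- label_map(mat, legend, mpp = 1)
  # cells at pixel centers: rows are y, columns x (0-based px + 0.5)
  at <- function(row, col) c(x = col - 0.5, y = row - 0.5)
  pts <- rbind(
    # villous epithelium: 4 enterocytes, 2 IELs, 1 goblet
    t(sapply(1:4, function(i) at(4, i))),
    t(sapply(1:2, function(i) at(5, i))),
    at(6, 1),
    # lamina propria: 2 plasma, 1 lymphocyte, 1 neutrophil, 1 eosinophil
    t(sapply(1:2, function(i) at(10, i))),
    at(11, 1), at(11, 2), at(11, 3),
    # crypt epithelium: 2 enterocytes, 1 IEL
    t(sapply(1:2, function(i) at(14, i))),
    at(15, 1)
  )
  classes <- c(rep("enterocyte", 4), rep("intraepithelial_lymphocyte", 2),
               "goblet_cell", rep("plasma_cell", 2), "lymphocyte",
               "neutrophil", "eosinophil", rep("enterocyte", 2),
               "intraepithelial_lymphocyte")
  cells <- cell_set(sprintf("h%02d", seq_along(classes)),
                    pts[, 1], pts[, 2], classes)
  slide_bundle(map, cells, grade = "0", slide_id = "hand")
}

# build a pure villous-epithelium frame holding exactly `n_ent` enterocytes
# and `n_iel` IELs on a regular grid (for lymphocytosis threshold tests)
iel_frame_bundle <- function(n_iel, n_ent = 100, seed = 1) {
  side <- 60L                      # 60 px at mpp 5 -> 300 um frame
  legend <- tissue_legend()
  map <- label_map(matrix(legend[["villous_epithelium"]], side, side),
                   legend, mpp = 5)
  n <- n_iel + n_ent
  g <- ceiling(sqrt(n))
  step <- side * 5 / (g + 1)
  xy <- expand.grid(ix = seq_len(g), iy = seq_len(g))[seq_len(n), ]
  withr::with_seed(seed, ord <- sample(n))
  classes <- c(rep("intraepithelial_lymphocyte", n_iel),
               rep("enterocyte", n_ent))[ord]
  cells <- cell_set(sprintf("f%04d", seq_len(n)),
                    xy$ix * step, xy$iy * step, classes)
  slide_bundle(map, cells, grade = "0",
               slide_id = sprintf("frame_iel%02d", n_iel))
}

# gridded true cells far enough apart that clustering is unambiguous
gridded_cells <- function(n, spacing_um = 12, classes = NULL, seed = 1) {
  g <- ceiling(sqrt(n))
  xy <- expand.grid(ix = seq_len(g), iy = seq_len(g))[seq_len(n), ]
  withr::with_seed(seed, {
    cls <- classes %||% sample(c("enterocyte", "intraepithelial_lymphocyte",
                                 "lymphocyte", "plasma_cell"),
                               n, replace = TRUE, prob = c(.4, .25, .2, .15))
  })
  cell_set(sprintf("g%05d", seq_len(n)), xy$ix * spacing_um,
           xy$iy * spacing_um, cls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
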