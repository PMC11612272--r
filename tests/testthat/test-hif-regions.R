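test_that("artifact exclusion recodes only masked pixels", {
  b <- hand_built_bundle()
  map <- b$label_map
  empty <- matrix(FALSE, nrow(map), ncol(map))
  expect_identical(unclass(apply_artifact_exclusion(map, empty)),
                   unclass(map))
  full <- !empty
  excluded <- apply_artifact_exclusion(map, full)
  expect_equal(region_area(excluded, "usable_tissue"), 0)
  # 25-px mask over villous pixels drops exactly the overlap
  mask <- empty; mask[3:7, 1:5] <- TRUE
  before <- class_pixel_counts(map)[["villous_epithelium"]]
  after <- class_pixel_counts(apply_artifact_exclusion(map, mask))[["villous_epithelium"]]
  expect_equal(before - after, 25L)
  expect_error(apply_artifact_exclusion(map, matrix(FALSE, 2, 2)),
               "shape")
})

test_that("region areas follow pixel count x mpp^2", {
  legend <- tissue_legend()
  mat <- matrix(legend[["background"]], 10, 10)
  mat[1:4, 1:10] <- legend[["villous_epithelium"]]   # 40 px
  m1 <- label_map(mat, legend, mpp = 1)
  expect_equal(region_area(m1, "villous_epithelium"), 4e-5)
  expect_equal(region_area(m1, "crypt_epithelium"), 0)
  m2 <- label_map(mat, legend, mpp = 2)
  expect_equal(region_area(m2, "villous_epithelium"),
               4 * region_area(m1, "villous_epithelium"))
})

test_that("area proportions are unitless ratios with NA for empty denominators", {
  legend <- tissue_legend()
  mat <- matrix(legend[["background"]], 10, 10)
  mat[1:3, ] <- legend[["villous_epithelium"]]       # 30 px
  mat[4:6, ] <- legend[["lamina_propria"]]           # 30 px
  m <- label_map(mat, legend, mpp = 0.5)
  expect_equal(area_proportion(m, "villous_epithelium", "villous_epithelium"), 1)
  expect_equal(area_proportion(m, "villous_epithelium", "mucosa"), 0.5)
  expect_true(is.na(area_proportion(m, "villous_epithelium", "crypt_epithelium")))
  mat[1:3, ] <- legend[["background"]]
  m0 <- label_map(mat, legend, mpp = 0.5)
  expect_equal(area_proportion(m0, "villous_epithelium", "mucosa"), 0)
})

test_that("cells map to pixels by floor(coord/mpp) with bounds warning", {
  legend <- tissue_legend()
  mat <- matrix(legend[["lamina_propria"]], 10, 10)
  mat[, 1:7] <- legend[["villous_epithelium"]]       # columns 1..7 villous
  m <- label_map(mat, legend, mpp = 2)
  # 10 cells, one per column center: 7 land on villous columns
  cells <- cell_set(sprintf("c%d", 1:10), seq(1, 19, by = 2), rep(5, 10),
                    rep("enterocyte", 10))
  expect_equal(nrow(cells_in_region(cells, m, "villous_epithelium")), 7L)
  expect_equal(nrow(cells_in_region(cell_set(), m, "villous_epithelium")), 0L)
  oob <- cell_set("z", 25, 5, "enterocyte")
  expect_warning(res <- cells_in_region(oob, m, "villous_epithelium"),
                 "outside")
  expect_equal(nrow(res), 0L)
})

test_that("densities and count proportions follow direct division", {
  legend <- tissue_legend()
  m <- label_map(matrix(legend[["villous_epithelium"]], 10, 10), legend,
                 mpp = sqrt(50))                     # area 0.005 mm^2
  iels <- cell_set(sprintf("i%d", 1:5), runif(5, 0, 10 * sqrt(50)),
                   runif(5, 0, 10 * sqrt(50)), rep("intraepithelial_lymphocyte", 5))
  expect_equal(cell_density(iels, "intraepithelial_lymphocyte", m,
                            "villous_epithelium"), 1000)
  expect_equal(cell_density(cell_set(), "intraepithelial_lymphocyte", m,
                            "villous_epithelium"), 0)
  b <- iel_frame_bundle(n_iel = 20, n_ent = 100)
  expect_equal(count_proportion(b$cells, "intraepithelial_lymphocyte",
                                "enterocyte", b$label_map,
                                "villous_epithelium"), 0.20)
  b31 <- iel_frame_bundle(n_iel = 31, n_ent = 100)
  expect_equal(count_proportion(b31$cells, "intraepithelial_lymphocyte",
                                "enterocyte", b31$label_map,
                                "villous_epithelium"), 0.31)
  expect_true(is.na(count_proportion(b$cells, "intraepithelial_lymphocyte",
                                     "enterocyte", b$label_map,
                                     "crypt_epithelium")))
})

test_that("proportions are invariant to mpp when geometry is fixed in um", {
  legend <- tissue_legend()
  base <- matrix(legend[["villous_epithelium"]], 20, 20)
  base[11:20, ] <- legend[["lamina_propria"]]
  cells <- cell_set(c("a", "b", "c"), c(5, 5, 5), c(2, 4, 15),
                    c("intraepithelial_lymphocyte", "enterocyte", "plasma_cell"))
  m1 <- label_map(base, legend, mpp = 1)            # 20 um extent
  m2 <- label_map(base[rep(1:20, each = 2), rep(1:20, each = 2)], legend,
                  mpp = 0.5)                        # same extent, finer px
  b1 <- slide_bundle(m1, cells, slide_id = "s")
  b2 <- slide_bundle(m2, cells, slide_id = "s")
  h1 <- extract_hifs(b1); h2 <- extract_hifs(b2)
  prop_cols <- grep("proportion", names(h1), value = TRUE)
  expect_equal(h1[prop_cols], h2[prop_cols])
  dens_cols <- grep("Density of", names(h1), value = TRUE)
  expect_equal(h1[dens_cols], h2[dens_cols])
})
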