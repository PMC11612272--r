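test_that("hand-built bundle features equal their hand computation", {
  b <- hand_built_bundle()
  h <- extract_hifs(b)
  # areas (px, mpp = 1): villous 120, LP 80, crypt 60, lumen 20, MM 20,
  # other 20; mucosa 300; epithelium 180; usable 320
  expect_equal(h[["Area proportion of villous epithelium over mucosa in tissue"]], 120 / 300)
  expect_equal(h[["Area proportion of villous epithelium over all epithelium in tissue"]], 120 / 180)
  expect_equal(h[["Area proportion of villous epithelium over lamina propria in tissue"]], 120 / 80)
  expect_equal(h[["Area proportion of crypt epithelium over usable tissue"]], 60 / 320)
  expect_equal(h[["Area proportion of lamina propria over crypt epithelium in tissue"]], 80 / 60)
  expect_equal(h[["Area proportion of crypt epithelium over all epithelium in tissue"]], 60 / 180)
  expect_equal(h[["Area proportion of crypt epithelium over mucosa in tissue"]], 60 / 300)
  expect_equal(h[["Area proportion of villous epithelium over crypt epithelium in tissue"]], 2)
  # cells: villous 4 ent + 2 IEL + 1 goblet; LP 2 plasma + 1 lymph + 1 neut
  # + 1 eos; crypt 2 ent + 1 IEL
  expect_equal(h[["Count proportion of intraepithelial lymphocytes over enterocytes in villous epithelium"]], 0.5)
  expect_equal(h[["Density of intraepithelial lymphocytes in villous epithelium"]], 2 / 120e-6)
  expect_equal(h[["Count proportion of plasma cells over all cells in lamina propria"]], 0.4)
  expect_equal(h[["Density of plasma cells in lamina propria"]], 2 / 80e-6)
  expect_equal(h[["Density of lymphocytes in lamina propria"]], 1 / 80e-6)
  expect_equal(h[["Count proportion of lymphocytes over all cells in lamina propria"]], 0.2)
  expect_equal(h[["Area proportion of lamina propria over mucosa in tissue"]], 80 / 300)
  expect_equal(h[["Total number of cells in lamina propria"]], 5)
  expect_equal(h[["Count proportion of neutrophils over all cells in mucosa"]], 1 / 15)
  expect_equal(h[["Count proportion of eosinophils over all cells in mucosa"]], 1 / 15)
  expect_equal(h[["Density of intraepithelial lymphocytes in crypt epithelium"]], 1 / 60e-6)
  expect_equal(h[["Density ratio of intraepithelial lymphocytes villous to crypt epithelium"]], 1)
})

test_that("masking non-tissue pixels only leaves the feature vector unchanged", {
  b <- hand_built_bundle()
  h0 <- extract_hifs(b)
  mask <- b$label_map == tissue_legend()[["background"]]
  b2 <- slide_bundle(b$label_map, b$cells, mask, grade = b$grade,
                     slide_id = b$slide_id)
  expect_equal(extract_hifs(b2), h0)
})

test_that("mucosal area proportions partition to exactly one", {
  for (seed in c(2, 9, 33)) {
    m <- simulate_label_map(sample(marsh_levels(), 1), shape = c(96, 96),
                            seed = seed)
    parts <- sapply(c("villous_epithelium", "crypt_epithelium", "crypt_lumen",
                      "lamina_propria", "muscularis_mucosa"),
                    function(k) area_proportion(m, k, "mucosa"))
    expect_equal(sum(parts), 1, tolerance = 1e-12)
  }
})

test_that("enlarging the artifact mask never increases any compartment area", {
  b <- random_tiny_bundle(101)
  small <- b$artifact_mask
  big <- small | (matrix(seq_len(length(small)), nrow(small)) %% 3 == 0)
  m_small <- apply_artifact_exclusion(b$label_map, small)
  m_big <- apply_artifact_exclusion(b$label_map, big)
  for (k in names(tissue_compartments())) {
    expect_lte(region_area(m_big, k), region_area(m_small, k))
  }
})

test_that("features match the brute-force oracle on tiny random bundles", {
  for (seed in 1:25) {
    b <- random_tiny_bundle(seed)
    expect_identical(unlist(extract_hifs(b)[, -1]), oracle_hifs(b),
                     label = paste("bundle", seed))
  }
})

test_that("lymphocytosis flag is strict at 30 per 100 enterocytes", {
  expect_true(iel_flag(0.31))
  expect_false(iel_flag(0.30))
  expect_false(iel_flag(0.20))
  expect_true(is.na(iel_flag(NA_real_)))
  h31 <- extract_hifs(iel_frame_bundle(31, 100))
  h30 <- extract_hifs(iel_frame_bundle(30, 100))
  expect_true(iel_flag(h31))
  expect_false(iel_flag(h30))
})

test_that("cohort grade-0 mean villous fraction calibrates to its target", {
  # 2-SE calibration check pooled over four independent 52-slide cohorts
  # (a single cohort's 95% interval misses by construction for ~1 seed in
  # 20; pooling raises replication without loosening the bound)
  v <- unlist(lapply(1:4, function(s) {
    coh <- simulate_cohort(c("0" = 52), shape = c(128, 128), seed = s)
    h <- extract_cohort_hifs(coh)
    h[["Area proportion of villous epithelium over mucosa in tissue"]]
  }))
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.33), 2 * se)
})
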