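test_that("Marsh grades map to consecutive ordinals", {
  expect_equal(marsh_to_ordinal("0"), 0L)
  expect_equal(marsh_to_ordinal("3a"), 3L)
  expect_equal(marsh_to_ordinal("3c"), 5L)
  expect_equal(marsh_to_ordinal(c("1", "2", "3b")), c(1L, 2L, 4L))
  expect_error(marsh_to_ordinal("4"), "unknown")
})

test_that("Spearman matches the classical formula and rank properties", {
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  r <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)                       # 1 - 6*2/(4*15)
  # invariance under strictly increasing transforms
  withr::with_seed(5, {
    x <- rnorm(30); y <- x + rnorm(30)
  })
  expect_equal(spearman(exp(x), y)$rho, spearman(x, y)$rho)
  # constant input is undefined, not 0
  expect_true(is.na(spearman(rep(1, 10), rnorm(10))$rho))
  expect_true(is.na(spearman(1:2, 2:1)$rho))     # n < 3
})

test_that("Spearman rho and p agree with cor.test on tied and untied data", {
  withr::with_seed(11, {
    for (k in 1:5) {
      n <- sample(5:40, 1)
      x <- sample(1:8, n, replace = TRUE)         # heavy ties
      y <- x + sample(-2:2, n, replace = TRUE)
      ours <- spearman(x, y)
      ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                              exact = FALSE))
      expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("Welch from summaries matches the raw-data Welch test", {
  withr::with_seed(7, {
    x <- rnorm(23, 1, 2); y <- rnorm(31, 0.2, 1.1)
  })
  ours <- welch_from_summary(mean(x), sd(x), length(x),
                             mean(y), sd(y), length(y))
  ref <- stats::t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  pooled <- welch_from_summary(mean(x), sd(x), length(x),
                               mean(y), sd(y), length(y), var_equal = TRUE)
  ref2 <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(pooled$df, unname(ref2$parameter))
})

test_that("Welch closed-form example and degenerate cases", {
  r <- welch_from_summary(1, 1, 10, 0, 1, 10)
  expect_equal(r$t, sqrt(5), tolerance = 1e-12)   # 1/sqrt(0.2)
  expect_equal(r$df, 18)
  expect_equal(r$p_value, 2 * pt(-sqrt(5), 18), tolerance = 1e-12)
  same <- welch_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  degen <- welch_from_summary(3, 0, 5, 3, 0, 5)
  expect_true(is.na(degen$t))
  expect_error(welch_from_summary(3, 0, 5, 4, 0, 5), "infinite")
})

test_that("swapping groups negates t and preserves p", {
  a <- welch_from_summary(0.33, 0.08, 52, 0.15, 0.07, 118)
  b <- welch_from_summary(0.15, 0.07, 118, 0.33, 0.08, 52)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
})

test_that("feature correlation table ranks by |rho| and drops constants from ranking", {
  withr::with_seed(21, {
    n <- 40
    grades <- sample(marsh_levels(), n, replace = TRUE)
    ord <- marsh_to_ordinal(grades)
    h <- tibble::tibble(
      slide_id = sprintf("s%02d", 1:n),
      up = ord + rnorm(n, 0, 0.5),
      down = -ord + rnorm(n, 0, 0.5),
      flat = rep(1, n),
      noise = rnorm(n)
    )
  })
  meta <- tibble::tibble(slide_id = h$slide_id, grade = grades)
  cors <- correlate_features(h, meta)
  expect_gt(cors$rho[cors$feature == "up"], 0)
  expect_lt(cors$rho[cors$feature == "down"], 0)
  expect_true(is.na(cors$rho[cors$feature == "flat"]))
  expect_equal(cors$feature[nrow(cors)], "flat")  # undefined ranked last
  # duplicating every slide leaves rho unchanged
  h2 <- dplyr::bind_rows(h, dplyr::mutate(h, slide_id = paste0(slide_id, "b")))
  meta2 <- dplyr::bind_rows(meta, dplyr::mutate(meta, slide_id = paste0(slide_id, "b")))
  cors2 <- correlate_features(h2, meta2)
  expect_equal(cors2$rho[cors2$feature == "up"],
               cors$rho[cors$feature == "up"], tolerance = 1e-12)
})

test_that("group comparison flags planted shifts and respects layout", {
  withr::with_seed(31, {
    h <- tibble::tibble(
      slide_id = sprintf("s%03d", 1:100),
      shifted = c(rnorm(50, 0), rnorm(50, 5)),    # 5 SD planted shift
      null = rnorm(100),
      sparse = c(rnorm(1), rep(NA, 99))
    )
  })
  meta <- tibble::tibble(slide_id = h$slide_id,
                         group = rep(c("normal", "celiac"), each = 50))
  cmp <- compare_groups(h, meta)
  expect_lt(cmp$p_value[cmp$feature == "shifted"], 1e-4)
  expect_gt(cmp$p_value[cmp$feature == "null"], 1e-4)
  expect_false("sparse" %in% cmp$feature)         # < 2 values in a group
  expect_equal(unique(cmp$group1), "normal")
  identical_groups <- compare_groups(
    tibble::tibble(slide_id = meta$slide_id, f = rep(c(1, 2), 50)), meta)
  expect_equal(identical_groups$p_value, 1)
  expect_error(compare_groups(h, tibble::tibble(slide_id = h$slide_id,
                                                group = "one")), "two groups")
  adj <- compare_groups(h, meta, adjust = TRUE)
  expect_true("p_adjusted" %in% names(adj))
})

test_that("split fractions reproduce dataset percentages to one decimal", {
  celiac <- split_fractions(230, 60, 28)
  expect_equal(celiac$percent, c(72.3, 18.9, 8.8))
  normal <- split_fractions(40, 12, 6)
  expect_equal(normal$percent, c(69.0, 20.7, 10.3))
  expect_equal(sum(celiac$n), 318L)
})
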