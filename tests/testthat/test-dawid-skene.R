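make_locations <- function(truth, labels_by_rater) {
  n <- length(truth)
  dplyr::bind_rows(purrr::imap(labels_by_rater, function(lab, rater) {
    tibble::tibble(location_id = sprintf("L%03d", seq_len(n)),
                   x_um = seq_len(n) * 10, y_um = 0,
                   labeler_id = rater, label = lab)
  }))
}

test_that("unanimous labels give back the unanimous classes and near-identity confusion", {
  truth <- rep(c("enterocyte", "lymphocyte", "plasma_cell"), each = 10)
  locs <- make_locations(truth, list(r1 = truth, r2 = truth, r3 = truth))
  fit <- estimate_truth(locs, prior_strength = 0.1)
  expect_equal(unname(fit$map_class), truth)
  for (th in fit$confusion) {
    expect_gt(min(diag(th)[c("enterocyte", "lymphocyte", "plasma_cell")]), 0.9)
  }
  expect_true(fit$converged)
})

test_that("a single labeler's posterior concentrates on their labels", {
  truth <- rep(c("enterocyte", "eosinophil"), each = 8)
  locs <- make_locations(truth, list(only = truth))
  fit <- estimate_truth(locs, prior_strength = 0.01)
  expect_equal(unname(fit$map_class), truth)
  # with one labeler the likelihood is flat along a label-switching ridge
  # and the smoothing prior softens the rows, so "concentrates" means
  # majority mass on the emitted label, not certainty
  expect_true(all(apply(fit$posterior, 1, max) > 0.6))
  expect_equal(colnames(fit$posterior)[apply(fit$posterior, 1, which.max)],
               truth)
})

test_that("the EM objective is non-decreasing across iterations", {
  withr::with_seed(3, {
    truth <- sample(c("enterocyte", "lymphocyte", "plasma_cell",
                      "intraepithelial_lymphocyte"), 120, replace = TRUE)
    noisy <- function() ifelse(runif(120) < 0.8, truth,
                               sample(names(cell_legend()), 120, replace = TRUE))
    locs <- make_locations(truth, list(r1 = noisy(), r2 = noisy(), r3 = noisy()))
  })
  fit <- estimate_truth(locs, tol = 1e-8, max_iter = 50)
  expect_true(all(diff(fit$log_posterior) > -1e-6))
})

test_that("absent emissions are non-informative and ties break to low codes", {
  truth <- rep("enterocyte", 6)
  labels <- list(r1 = truth,
                 r2 = c(truth[1:3], rep("absent", 3)))
  locs <- make_locations(truth, labels)
  fit <- estimate_truth(locs)
  expect_equal(unname(fit$map_class), truth)
  # two labelers disagreeing symmetrically: tie resolves to lower code
  locs2 <- make_locations(rep("lymphocyte", 4),
                          list(a = rep("plasma_cell", 4),
                               b = rep("lymphocyte", 4)))
  fit2 <- estimate_truth(locs2, max_iter = 1L)
  expect_true(all(fit2$map_class == "plasma_cell"))   # code 2 < code 5
  expect_error(estimate_truth(make_locations("enterocyte",
                                             list(a = "absent"))), "no labels")
})

test_that("planted confusions and truth are recovered from simulated raters", {
  n <- 400
  cells <- gridded_cells(n, spacing_um = 12, seed = 9)
  profiles <- purrr::map(1:3, function(j) {
    rater_profile(paste0("r", j), confusion = planted_confusion(0.9),
                  position_jitter_sd = 0.8)
  })
  ann <- simulate_raters(cells, profiles, seed = 15,
                         bounds_um = c(300, 300))
  locs <- cluster_annotations(ann, link_radius_um = 4)
  fit <- estimate_truth(locs, prior_strength = 0.1)
  present <- c("enterocyte", "intraepithelial_lymphocyte", "lymphocyte",
               "plasma_cell")
  for (th in fit$confusion) {
    expect_true(all(abs(diag(th)[present] - 0.9) < 0.05))
  }
  # match each location back to the nearest true cell
  ids <- rownames(fit$posterior)
  xy <- dplyr::distinct(locs[, c("location_id", "x_um", "y_um")])
  xy <- xy[match(ids, xy$location_id), ]
  truth <- cells$cell_class[vapply(seq_len(nrow(xy)), function(i) {
    which.min((cells$x_um - xy$x_um[i])^2 + (cells$y_um - xy$y_um[i])^2)
  }, 1L)]
  expect_gte(mean(fit$map_class == truth), 0.95)
})

test_that("tidy and glance summarize the fit in broom style", {
  truth <- rep(c("enterocyte", "lymphocyte"), each = 6)
  fit <- estimate_truth(make_locations(truth, list(r1 = truth, r2 = truth)))
  td <- tidy(fit)
  expect_setequal(names(td),
                  c("labeler_id", "true_class", "emitted_class", "probability"))
  expect_equal(nrow(td), 2 * 8 * 8)
  sums <- dplyr::summarise(dplyr::group_by(td, labeler_id, true_class),
                           s = sum(probability))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  gl <- glance(fit)
  expect_equal(gl$n_labelers, 2L)
  expect_equal(gl$n_locations, 12L)
})
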