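ann_row <- function(labeler, x, y, cls = "enterocyte") {
  tibble::tibble(labeler_id = labeler, x_um = x, y_um = y, cell_class = cls)
}

test_that("points closer than the radius merge, farther ones do not", {
  near <- dplyr::bind_rows(ann_row("a", 10, 10), ann_row("b", 10.8, 10.4))
  locs <- cluster_annotations(near, link_radius_um = 4)
  expect_equal(length(unique(locs$location_id)), 1L)
  expect_setequal(locs$label, c("enterocyte", "enterocyte"))
  far <- dplyr::bind_rows(ann_row("a", 10, 10), ann_row("b", 20, 10))
  locs2 <- cluster_annotations(far, link_radius_um = 4)
  expect_equal(length(unique(locs2$location_id)), 2L)
  # the labeler missing from each far location is recorded as absent
  expect_equal(sum(locs2$label == "absent"), 2L)
})

test_that("a single labeler yields one location per point with labels kept", {
  ann <- dplyr::bind_rows(
    ann_row("solo", 5, 5, "lymphocyte"),
    ann_row("solo", 50, 50, "plasma_cell"),
    ann_row("solo", 100, 100, "eosinophil")
  )
  locs <- cluster_annotations(ann, link_radius_um = 4)
  expect_equal(length(unique(locs$location_id)), 3L)
  expect_setequal(locs$label[locs$label != "absent"],
                  c("lymphocyte", "plasma_cell", "eosinophil"))
})

test_that("clusters with duplicate labeler points are split by nearest seed", {
  ann <- dplyr::bind_rows(
    ann_row("a", 10, 10), ann_row("a", 13, 10),   # 3 um apart, same labeler
    ann_row("b", 10.5, 10), ann_row("b", 12.8, 10)
  )
  locs <- cluster_annotations(ann, link_radius_um = 4)
  expect_equal(length(unique(locs$location_id)), 2L)
  counted <- locs[locs$label != "absent", ]
  per_loc <- table(counted$location_id, counted$labeler_id)
  expect_true(all(per_loc <= 1L))
})

test_that("clustering is invariant to labeler order and translation", {
  withr::with_seed(42, {
    base <- dplyr::bind_rows(purrr::map(1:3, function(j) {
      n <- 30
      ann_row(paste0("r", j), runif(n, 0, 300), runif(n, 0, 300),
              sample(names(cell_legend()), n, replace = TRUE))
    }))
  })
  a <- cluster_annotations(base, 4)
  b <- cluster_annotations(base[sample(nrow(base)), ], 4)
  key <- function(l) {
    k <- l[l$label != "absent", ]
    k <- k[order(k$x_um, k$y_um, k$labeler_id), c("x_um", "y_um", "labeler_id", "label")]
    rownames(k) <- NULL
    k
  }
  expect_equal(key(a), key(b))
  shifted <- dplyr::mutate(base, x_um = x_um + 1000, y_um = y_um + 500)
  c <- cluster_annotations(shifted, 4)
  kc <- key(c); ka <- key(a)
  expect_equal(kc$x_um, ka$x_um + 1000)
  expect_equal(kc$label, ka$label)
})

test_that("per-frame clustering respects frame boundaries", {
  frames <- tibble::tibble(frame_id = c("f1", "f2"), x0_um = c(0, 100),
                           y0_um = c(0, 0), side_um = 50)
  ann <- dplyr::bind_rows(ann_row("a", 10, 10), ann_row("a", 110, 10))
  fa <- annotations_in_frames(ann, frames)
  expect_equal(sort(unique(fa$frame_id)), c("f1", "f2"))
  locs <- cluster_annotations(fa, 4)
  expect_equal(length(unique(locs$location_id)), 2L)
})

test_that("frame sampling gives disjoint in-bounds frames deterministically", {
  b <- simulate_slide("0", shape = c(512, 512), mpp = 1, seed = 5)
  fr <- sample_frames(b, n_frames = 20, side_um = 75, seed = 9)
  expect_equal(nrow(fr), 20L)
  expect_true(all(fr$x0_um >= 0 & fr$x0_um + 75 <= 512))
  for (i in 1:19) for (j in (i + 1):20) {
    expect_true(abs(fr$x0_um[i] - fr$x0_um[j]) >= 75 ||
                  abs(fr$y0_um[i] - fr$y0_um[j]) >= 75)
  }
  fr2 <- sample_frames(b, n_frames = 20, side_um = 75, seed = 9)
  expect_identical(fr, fr2)
  expect_error(sample_frames(b, n_frames = 2, side_um = 600, seed = 1),
               "smaller")
  expect_error(sample_frames(b, n_frames = 60, side_um = 75, seed = 1,
                             max_tries = 100L), "non-overlapping")
})
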