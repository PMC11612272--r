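#' Define a simulated annotator's error profile
#'
#' A rater profile parameterizes how a simulated pathologist (or a cell
#' model treated as one more labeler) corrupts the true cell set: per-class
#' detection rates, a row-stochastic label confusion matrix, isotropic
#' position jitter, and an area-density of spurious detections.
#'
#' @param labeler_id Identifier string.
#' @param confusion Square row-stochastic matrix over [cell_legend()]
#'   classes (rows = true class, columns = emitted label); rows must sum to
#'   1 within 1e-9. Default identity.
#' @param detection_rate Per-class probability of detecting a true cell, in
#'   [0, 1]; scalar or named vector. Default 1.
#' @param false_positive_rate Spurious detections per mm^2. Default 0.
#' @param position_jitter_sd Isotropic jitter SD in microns. Default 0.
#' @return A `rater_profile` list.
#' @export
rater_profile <- function(labeler_id, confusion = NULL, detection_rate = 1,
                          false_positive_rate = 0, position_jitter_sd = 0) {
  classes <- names(cell_legend())
  K <- length(classes)
  if (is.null(confusion)) confusion <- diag(K)
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == K)) {
    stop("confusion must be ", K, " x ", K, " over the cell legend",
         call. = FALSE)
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-9) || any(confusion < 0)) {
    stop("confusion rows must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  dimnames(confusion) <- list(classes, classes)
  if (length(detection_rate) == 1L) {
    detection_rate <- stats::setNames(rep(detection_rate, K), classes)
  }
  detection_rate <- detection_rate[classes]
  if (any(is.na(detection_rate)) || any(detection_rate < 0 | detection_rate > 1)) {
    stop("detection_rate must cover all classes with values in [0, 1]",
         call. = FALSE)
  }
  stopifnot(false_positive_rate >= 0, position_jitter_sd >= 0)
  structure(
    list(labeler_id = labeler_id, confusion = confusion,
         detection_rate = detection_rate,
         false_positive_rate = false_positive_rate,
         position_jitter_sd = position_jitter_sd),
    class = "rater_profile"
  )
}

#' Simulate multi-annotator point labels for a cell set
#'
#' For each rater profile, each true cell is detected with its class's
#' detection rate; a detected cell's emitted label is drawn from the
#' confusion row of its true class and its position is jittered; false
#' positives are added as a homogeneous Poisson process over the slide with
#' uniformly random labels. This is the generator-side inverse of the
#' consensus estimation: [estimate_truth()] should recover the planted
#' confusion matrices.
#'
#' @param cells True cell set tibble.
#' @param profiles List of [rater_profile()]s (at least one).
#' @param seed Integer seed; deterministic given seed.
#' @param bounds_um Slide extent `c(width, height)` in microns, used for
#'   false-positive placement; inferred from the cells if `NULL`.
#' @return Annotation tibble: `labeler_id`, `source_id` (true `cell_id`, or
#'   `NA` for false positives), `x_um`, `y_um`, `cell_class`.
#' @export
simulate_raters <- function(cells, profiles, seed = 1L, bounds_um = NULL) {
  if (!length(profiles)) stop("need at least one rater profile", call. = FALSE)
  if (inherits(profiles, "rater_profile")) profiles <- list(profiles)
  cells <- validate_cell_set(cells)
  classes <- names(cell_legend())
  if (is.null(bounds_um)) {
    bounds_um <- if (nrow(cells)) c(max(cells$x_um), max(cells$y_um)) else c(1, 1)
  }
  area_mm2 <- prod(bounds_um) * 1e-6

  withr::with_seed(seed, {
    out <- purrr::map(profiles, function(p) {
      det <- if (nrow(cells)) {
        stats::runif(nrow(cells)) < p$detection_rate[cells$cell_class]
      } else logical()
      hit <- cells[det, , drop = FALSE]
      lab <- vapply(hit$cell_class, function(cl) {
        sample(classes, 1L, prob = p$confusion[cl, ])
      }, character(1), USE.NAMES = FALSE)
      jx <- if (p$position_jitter_sd > 0) {
        stats::rnorm(nrow(hit), 0, p$position_jitter_sd)
      } else rep(0, nrow(hit))
      jy <- if (p$position_jitter_sd > 0) {
        stats::rnorm(nrow(hit), 0, p$position_jitter_sd)
      } else rep(0, nrow(hit))
      ann <- tibble::tibble(
        labeler_id = p$labeler_id,
        source_id = hit$cell_id,
        x_um = hit$x_um + jx,
        y_um = hit$y_um + jy,
        cell_class = lab
      )
      n_fp <- stats::rpois(1, p$false_positive_rate * area_mm2)
      if (n_fp > 0L) {
        ann <- dplyr::bind_rows(ann, tibble::tibble(
          labeler_id = p$labeler_id,
          source_id = NA_character_,
          x_um = stats::runif(n_fp, 0, bounds_um[1]),
          y_um = stats::runif(n_fp, 0, bounds_um[2]),
          cell_class = sample(classes, n_fp, replace = TRUE)
        ))
      }
      ann
    })
    dplyr::bind_rows(out)
  })
}
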