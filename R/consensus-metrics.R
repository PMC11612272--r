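#' Per-labeler sensitivity, specificity and observed confusion
#'
#' Scores each labeler (pathologist or model) against the consensus truth,
#' one-vs-rest per cell class: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). An `"absent"` emission counts as a negative prediction for
#' every class. Sensitivity is `NA` for classes absent from the truth; the
#' specificity is still computed. The observed confusion matrix
#' (row-normalized over truth classes, `"absent"` excluded) is available
#' via [labeler_confusion()].
#'
#' @param truth Named character vector of MAP classes per location (from
#'   [estimate_truth()]`$map_class`), or a `dawid_skene` fit.
#' @param locations Long `consensus_locations` tibble; defaults to the one
#'   stored in the fit when `truth` is a fit.
#' @return Tibble: `labeler_id`, `cell_class`, `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity`.
#' @export
labeler_metrics <- function(truth, locations = NULL) {
  if (inherits(truth, "dawid_skene")) {
    locations <- locations %||% truth$locations
    truth <- truth$map_class
  }
  stopifnot(!is.null(locations))
  classes <- names(cell_legend())
  loc <- locations
  loc$truth <- unname(truth[loc$location_id])
  if (any(is.na(loc$truth))) {
    stop("truth and locations are not aligned on location_id", call. = FALSE)
  }
  combos <- tidyr::crossing(labeler_id = sort(unique(loc$labeler_id)),
                            cell_class = classes)
  purrr::pmap(combos, function(labeler_id, cell_class) {
    m <- loc[loc$labeler_id == labeler_id, , drop = FALSE]
    pos_pred <- m$label == cell_class            # "absent" is negative
    pos_true <- m$truth == cell_class
    tp <- sum(pos_pred & pos_true)
    fn <- sum(!pos_pred & pos_true)
    fp <- sum(pos_pred & !pos_true)
    tn <- sum(!pos_pred & !pos_true)
    tibble::tibble(
      labeler_id = labeler_id, cell_class = cell_class,
      tp = tp, fn = fn, fp = fp, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  }) |> dplyr::bind_rows()
}

#' Observed row-normalized confusion matrix of one labeler
#'
#' Cross-tabulates consensus truth classes against the labeler's emitted
#' labels at locations where the labeler emitted one (`"absent"` is a
#' detection failure, not a class, and is excluded), then normalizes rows.
#'
#' @inheritParams labeler_metrics
#' @param labeler_id Which labeler to tabulate.
#' @return A K x K matrix (truth x emitted) with rows summing to 1 (or 0
#'   for truth classes never seen by this labeler).
#' @export
labeler_confusion <- function(truth, labeler_id, locations = NULL) {
  if (inherits(truth, "dawid_skene")) {
    locations <- locations %||% truth$locations
    truth <- truth$map_class
  }
  classes <- names(cell_legend())
  m <- locations[locations$labeler_id == labeler_id &
                   locations$label != "absent", , drop = FALSE]
  tr <- factor(unname(truth[m$location_id]), levels = classes)
  em <- factor(m$label, levels = classes)
  tab <- table(tr, em)
  out <- matrix(as.numeric(tab), length(classes), length(classes),
                dimnames = list(classes, classes))
  rs <- rowSums(out)
  out[rs > 0, ] <- out[rs > 0, , drop = FALSE] / rs[rs > 0]
  out
}
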