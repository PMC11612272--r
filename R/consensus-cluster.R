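#' Sample non-overlapping validation frames from a slide
#'
#' Draws square frames uniformly over the slide, rejecting overlaps, up to
#' a retry cap. Frames of 75 um x 75 um are the conventional unit for
#' exhaustive multi-annotator cell validation.
#'
#' @param bundle A [slide_bundle()] (or a [label_map()]).
#' @param n_frames Number of frames (>= 1).
#' @param side_um Frame side length in microns (default 75).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per run (default `1000 * n_frames`).
#' @return Tibble: `frame_id`, `x0_um`, `y0_um`, `side_um`.
#' @export
sample_frames <- function(bundle, n_frames, side_um = 75, seed = 1L,
                          max_tries = 1000L * n_frames) {
  map <- if (inherits(bundle, "slide_bundle")) bundle$label_map else bundle
  stopifnot(inherits(map, "label_map"), n_frames >= 1, side_um > 0)
  w_um <- ncol(map) * map_mpp(map)
  h_um <- nrow(map) * map_mpp(map)
  if (side_um > w_um || side_um > h_um) {
    stop("slide (", round(w_um, 1), " x ", round(h_um, 1),
         " um) is smaller than the frame", call. = FALSE)
  }
  withr::with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L; stuck <- 0L
    while (length(xs) < n_frames && tries < max_tries) {
      tries <- tries + 1L
      x <- stats::runif(1, 0, w_um - side_um)
      y <- stats::runif(1, 0, h_um - side_um)
      if (!length(xs) ||
          all(abs(xs - x) >= side_um | abs(ys - y) >= side_um)) {
        xs <- c(xs, x); ys <- c(ys, y)
        stuck <- 0L
      } else {
        # a partial greedy placement can be a dead end (e.g. one frame in
        # the middle of a tight slide); restart rather than spin
        stuck <- stuck + 1L
        if (stuck >= 200L) {
          xs <- numeric(0); ys <- numeric(0); stuck <- 0L
        }
      }
    }
    if (length(xs) < n_frames) {
      stop("could not place ", n_frames, " non-overlapping frames after ",
           max_tries, " tries", call. = FALSE)
    }
    tibble::tibble(
      frame_id = sprintf("f%03d", seq_len(n_frames)),
      x0_um = xs, y0_um = ys, side_um = side_um
    )
  })
}

#' Restrict annotations (or cells) to sampled frames
#'
#' @param ann Tibble with `x_um`, `y_um` columns (annotations or cells).
#' @param frames Frame tibble from [sample_frames()].
#' @return `ann` rows falling inside a frame, with a `frame_id` column.
#' @export
annotations_in_frames <- function(ann, frames) {
  purrr::pmap(frames, function(frame_id, x0_um, y0_um, side_um, ...) {
    hit <- ann$x_um >= x0_um & ann$x_um < x0_um + side_um &
      ann$y_um >= y0_um & ann$y_um < y0_um + side_um
    if (!any(hit)) return(NULL)
    dplyr::bind_cols(tibble::tibble(frame_id = frame_id),
                     ann[hit, , drop = FALSE])
  }) |> dplyr::bind_rows()
}

#' Cluster multi-labeler point annotations into consensus locations
#'
#' Single-linkage agglomeration of all labelers' points, cut at
#' `link_radius_um`, identifies putative cell locations: points from
#' different labelers that refer to the same cell. Clusters containing two
#' points from the same labeler are split by nearest assignment to that
#' labeler's points (recursively, so no final location holds two points
#' from one labeler). Each location's representative point is the centroid
#' of its members; labelers with no point in a location are recorded as
#' `"absent"`.
#'
#' @param ann Annotation tibble: `labeler_id`, `x_um`, `y_um`,
#'   `cell_class`, optional `frame_id` (clustering is per frame when
#'   present).
#' @param link_radius_um Linkage cut height in microns (default 4, about a
#'   lymphocyte radius).
#' @return A `consensus_locations` tibble in long form: `location_id`,
#'   `x_um`, `y_um` (centroid), `labeler_id`, `label` (an emitted class or
#'   `"absent"`), plus `frame_id` when supplied. One row per location x
#'   labeler.
#' @export
cluster_annotations <- function(ann, link_radius_um = 4) {
  stopifnot(link_radius_um > 0)
  req <- c("labeler_id", "x_um", "y_um", "cell_class")
  if (!all(req %in% names(ann))) {
    stop("annotations need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  labelers <- sort(unique(ann$labeler_id))
  groups <- if ("frame_id" %in% names(ann)) split(ann, ann$frame_id) else list(ann)

  loc_list <- purrr::imap(groups, function(g, key) {
    if (!nrow(g)) return(NULL)
    cl <- cut_clusters(g$x_um, g$y_um, link_radius_um)
    pieces <- split(seq_len(nrow(g)), cl)
    pieces <- purrr::map(pieces, function(ix) split_by_labeler(g, ix)) |>
      purrr::flatten()
    purrr::map(pieces, function(ix) {
      m <- g[ix, , drop = FALSE]
      tibble::tibble(
        frame_id = if ("frame_id" %in% names(m)) m$frame_id[1] else NA_character_,
        x_um = mean(m$x_um), y_um = mean(m$y_um),
        labeler_id = list(m$labeler_id), label = list(m$cell_class)
      )
    }) |> dplyr::bind_rows()
  })
  locs <- dplyr::bind_rows(loc_list)
  if (!nrow(locs)) {
    return(structure(tibble::tibble(
      location_id = character(), frame_id = character(), x_um = numeric(),
      y_um = numeric(), labeler_id = character(), label = character()
    ), class = c("consensus_locations", class(tibble::tibble()))))
  }
  locs <- locs[order(locs$x_um, locs$y_um), , drop = FALSE]
  locs$location_id <- sprintf("L%05d", seq_len(nrow(locs)))

  long <- tidyr::crossing(
    locs[, c("location_id", "frame_id", "x_um", "y_um")],
    labeler_id = labelers
  )
  emitted <- locs |>
    dplyr::select("location_id", "labeler_id", "label") |>
    tidyr::unnest(c("labeler_id", "label"))
  long <- dplyr::left_join(long, emitted,
                           by = c("location_id", "labeler_id")) |>
    dplyr::mutate(label = dplyr::coalesce(.data$label, "absent")) |>
    dplyr::arrange(.data$location_id, .data$labeler_id)
  if (all(is.na(long$frame_id))) long$frame_id <- NULL
  structure(long, class = c("consensus_locations", class(long)))
}

# single-linkage clusters cut at `radius`
cut_clusters <- function(x, y, radius) {
  n <- length(x)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(cbind(x, y)), method = "single")
  stats::cutree(hc, h = radius)
}

# Split a cluster whose members include >1 point from one labeler: seed on
# the most-duplicated labeler's points, assign every point to its nearest
# seed, recurse until all pieces are labeler-unique.
split_by_labeler <- function(g, ix) {
  tab <- table(g$labeler_id[ix])
  if (all(tab <= 1L)) return(list(ix))
  dup <- names(tab)[which.max(tab)]
  seeds <- ix[g$labeler_id[ix] == dup]
  d2 <- outer(ix, seeds, function(a, b) {
    (g$x_um[a] - g$x_um[b])^2 + (g$y_um[a] - g$y_um[b])^2
  })
  assign <- apply(d2, 1L, which.min)
  pieces <- split(ix, assign)
  purrr::flatten(purrr::map(pieces, function(p) split_by_labeler(g, p)))
}
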