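#' Simulate a complete graded slide
#'
#' Composes [simulate_label_map()], [populate_cells()], and an artifact mask
#' (random blobs over tissue covering approximately the grade's
#' `artifact_fraction` of tissue pixels) into one [slide_bundle()].
#'
#' @inheritParams simulate_label_map
#' @param slide_id Identifier recorded in the bundle.
#' @return A [slide_bundle()].
#' @export
simulate_slide <- function(grade, params = grade_params(grade),
                           shape = c(512, 512), mpp = 0.25, seed = 1L,
                           slide_id = paste0("slide_g", grade)) {
  map <- simulate_label_map(grade, params, shape, mpp, derive_seed(seed, 1))
  cells <- populate_cells(map, params, derive_seed(seed, 2))
  mask <- simulate_artifact_mask(map, params$artifact_fraction,
                                 derive_seed(seed, 3))
  slide_bundle(map, cells, mask, grade = grade, slide_id = slide_id)
}

#' Simulate an artifact mask over tissue
#'
#' Accumulates random disk-shaped blobs centered on tissue pixels until the
#' masked fraction of tissue reaches `fraction` (debris, folds and
#' out-of-focus regions are blob-like at slide scale).
#'
#' @param map A [label_map()].
#' @param fraction Target fraction of tissue pixels to cover, in [0, 1].
#' @param seed Integer seed.
#' @return Logical matrix with the map's shape.
#' @export
simulate_artifact_mask <- function(map, fraction, seed = 1L) {
  H <- nrow(map); W <- ncol(map)
  mask <- matrix(FALSE, H, W)
  if (fraction <= 0) return(mask)
  legend <- map_legend(map)
  tissue <- map != legend[["background"]]
  n_tissue <- sum(tissue)
  if (n_tissue == 0L) return(mask)
  withr::with_seed(seed, {
    idx_tissue <- which(tissue)
    r <- max(2, round(0.03 * min(H, W)))
    guard <- 0L
    while (sum(mask & tissue) < fraction * n_tissue && guard < 10000L) {
      ctr <- idx_tissue[sample.int(length(idx_tissue), 1L)]
      cy <- (ctr - 1L) %% H + 1L
      cx <- (ctr - 1L) %/% H + 1L
      mask[disk_indices(cy, cx, r, H, W)] <- TRUE
      guard <- guard + 1L
    }
  })
  mask
}

#' Simulate a graded cohort of slides
#'
#' Generates one [slide_bundle()] per requested slide, with deterministic
#' per-slide child seeds derived from the root seed, and a metadata table
#' assigning each slide its grade and its normal/celiac group (grade 0 is
#' normal, all others celiac).
#'
#' @param n_per_grade Named integer vector, names from [marsh_levels()],
#'   e.g. `c("0" = 52, "1" = 24, ...)`; counts >= 0.
#' @param params Either `NULL` (defaults per grade), a function
#'   `grade -> grade_params`, or a named list of [grade_params()] by grade.
#' @inheritParams simulate_label_map
#' @return A list with `slides` (list of bundles) and `metadata` (tibble
#'   `slide_id`, `grade`, `group`).
#' @export
#' @examples
#' coh <- simulate_cohort(c("0" = 2, "3c" = 2), shape = c(96, 96), seed = 1)
#' coh$metadata
simulate_cohort <- function(n_per_grade, params = NULL,
                            shape = c(512, 512), mpp = 0.25, seed = 1L) {
  stopifnot(!is.null(names(n_per_grade)))
  bad <- setdiff(names(n_per_grade), marsh_levels())
  if (length(bad)) stop("unknown grade(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(n_per_grade < 0)) stop("counts must be >= 0", call. = FALSE)
  get_params <- function(g) {
    if (is.null(params)) grade_params(g)
    else if (is.function(params)) params(g)
    else params[[g]]
  }
  grades <- rep(names(n_per_grade), times = as.integer(n_per_grade))
  slides <- vector("list", length(grades))
  ids <- character(length(grades))
  for (i in seq_along(grades)) {
    g <- grades[i]
    ids[i] <- sprintf("s%03d_g%s", i, g)
    slides[[i]] <- simulate_slide(g, get_params(g), shape, mpp,
                                  seed = derive_seed(seed, 100L + i),
                                  slide_id = ids[i])
  }
  metadata <- tibble::tibble(
    slide_id = ids,
    grade = grades,
    group = ifelse(grades == "0", "normal", "celiac")
  )
  list(slides = slides, metadata = metadata)
}
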