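#' Pipeline configuration
#'
#' Collects every tunable the end-to-end run needs. Round-trips losslessly
#' through YAML ([write_config()] / [read_config()]); all numeric
#' constraints of the downstream stages are enforced at construction.
#'
#' @param n_per_grade Named counts of slides per Marsh grade.
#' @param shape Slide raster dimensions `c(rows, cols)`, each >= 64.
#' @param mpp Microns per pixel (> 0).
#' @param seed Root integer seed; all stage seeds derive from it.
#' @param link_radius_um Annotation clustering radius (> 0).
#' @param prior_strength Dawid-Skene Dirichlet smoothing (>= 0).
#' @param test_flavor `"welch"` or `"student"` for the group comparison.
#' @param n_frames Validation frames sampled per validated slide.
#' @param frame_side_um Validation frame side length in microns.
#' @param n_raters Simulated pathologists for the validation stage.
#' @param extended Include extended crypt-IEL features.
#' @param grade_overrides Named list: grade -> list of [grade_params()]
#'   overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_grade = c("0" = 52, "1" = 24, "2" = 24,
                                            "3a" = 24, "3b" = 23, "3c" = 23),
                            shape = c(768, 768), mpp = 1.0, seed = 1L,
                            link_radius_um = 4, prior_strength = 0.1,
                            test_flavor = c("welch", "student"),
                            n_frames = 20L, frame_side_um = 75,
                            n_raters = 5L, extended = TRUE,
                            grade_overrides = list()) {
  test_flavor <- match.arg(test_flavor)
  stopifnot(
    !is.null(names(n_per_grade)), all(n_per_grade >= 0),
    all(names(n_per_grade) %in% marsh_levels()),
    length(shape) == 2L, all(shape >= 64), mpp > 0,
    link_radius_um > 0, prior_strength >= 0,
    n_frames >= 1, frame_side_um > 0, n_raters >= 1
  )
  structure(
    list(
      n_per_grade = stats::setNames(as.integer(n_per_grade), names(n_per_grade)),
      shape = as.integer(shape), mpp = as.numeric(mpp),
      seed = as.integer(seed),
      link_radius_um = as.numeric(link_radius_um),
      prior_strength = as.numeric(prior_strength),
      test_flavor = test_flavor,
      n_frames = as.integer(n_frames),
      frame_side_um = as.numeric(frame_side_um),
      n_raters = as.integer(n_raters),
      extended = isTRUE(extended),
      grade_overrides = grade_overrides
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- unclass(config)
  raw$n_per_grade <- as.list(raw$n_per_grade)   # keep grade names in YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$n_per_grade <- unlist(raw$n_per_grade)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

config_grade_params <- function(config, grade) {
  ov <- config$grade_overrides[[grade]]
  if (is.null(ov)) grade_params(grade) else do.call(grade_params, c(list(grade), ov))
}

#' Run the full pipeline: simulate, extract, validate, correlate, compare
#'
#' Executes the stages end to end under one root seed: cohort simulation,
#' per-slide HIF extraction, cell-call validation on sampled frames of the
#' first slide (simulated raters, clustering, Dawid-Skene consensus,
#' per-labeler metrics), Spearman correlation with Marsh grade, and the
#' normal-vs-celiac group comparison. All tables are written as CSV under
#' `out_dir`, together with a JSON run manifest (config hash, package
#' version, per-stage outputs, seeds, timestamps). Fixed seeds give
#' byte-identical CSV outputs across runs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param write_slides Also write every slide's raster/cells/mask (default
#'   FALSE; the feature table is usually what downstream work needs).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, out_dir, write_slides = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("celiachif")),
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  outputs <- character(0)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$partial <<- TRUE
      write_manifest(manifest, out_dir)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     outputs = as.character(res %||% character()))
    outputs <<- c(outputs, res %||% character())
    res
  }

  empty <- sum(config$n_per_grade) == 0L

  cohort <- NULL
  stage("simulate", function() {
    cohort <<- simulate_cohort(config$n_per_grade,
                               params = function(g) config_grade_params(config, g),
                               shape = config$shape, mpp = config$mpp,
                               seed = derive_seed(config$seed, 1))
    meta_path <- file.path(out_dir, "metadata.csv")
    write_metadata(cohort$metadata, meta_path)
    slide_paths <- character(0)
    if (write_slides && length(cohort$slides)) {
      slide_paths <- unlist(purrr::map(
        cohort$slides, write_slide_bundle, dir = file.path(out_dir, "slides")))
    }
    c(meta_path, slide_paths)
  })

  features <- NULL
  stage("extract", function() {
    features <<- extract_cohort_hifs(cohort, extended = config$extended)
    path <- file.path(out_dir, "features.csv")
    if (is.null(features) || !nrow(features)) {
      features <<- tibble::tibble(slide_id = character())
    }
    readr::write_csv(features, path)
    path
  })

  stage("validate_cells", function() {
    if (empty) return(character())
    bundle <- cohort$slides[[1]]
    frames <- sample_frames(bundle, config$n_frames, config$frame_side_um,
                            seed = derive_seed(config$seed, 2))
    frame_cells <- annotations_in_frames(bundle$cells, frames)
    if (!nrow(frame_cells)) return(character())
    profiles <- purrr::map(seq_len(config$n_raters), function(j) {
      rater_profile(sprintf("pathologist_%d", j),
                    confusion = planted_confusion(0.9),
                    detection_rate = 0.95, position_jitter_sd = 1)
    })
    profiles <- c(profiles, list(rater_profile("model",
                                               confusion = planted_confusion(0.92),
                                               detection_rate = 0.97,
                                               position_jitter_sd = 0.5)))
    ann <- simulate_raters(frame_cells, profiles,
                           seed = derive_seed(config$seed, 3),
                           bounds_um = c(ncol(bundle$label_map),
                                         nrow(bundle$label_map)) * config$mpp)
    ann <- annotations_in_frames(ann[, setdiff(names(ann), "frame_id")], frames)
    locs <- cluster_annotations(ann, config$link_radius_um)
    fit <- estimate_truth(locs, prior_strength = config$prior_strength)
    metrics <- labeler_metrics(fit)
    p_cons <- file.path(out_dir, "consensus.csv")
    p_metr <- file.path(out_dir, "labeler_metrics.csv")
    cons <- tibble::as_tibble(fit$posterior) |>
      dplyr::mutate(location_id = rownames(fit$posterior),
                    map_class = unname(fit$map_class), .before = 1L)
    readr::write_csv(cons, p_cons)
    readr::write_csv(metrics, p_metr)
    c(p_cons, p_metr)
  })

  stage("correlate", function() {
    path <- file.path(out_dir, "correlations.csv")
    if (empty || !nrow(features)) {
      readr::write_csv(tibble::tibble(feature = character(), rho = numeric(),
                                      p_value = numeric(), n = integer()), path)
      return(path)
    }
    readr::write_csv(correlate_features(features, cohort$metadata), path)
    path
  })

  stage("compare", function() {
    path <- file.path(out_dir, "group_comparison.csv")
    if (empty || length(unique(cohort$metadata$group)) != 2L) {
      readr::write_csv(tibble::tibble(feature = character()), path)
      return(path)
    }
    readr::write_csv(
      compare_groups(features, cohort$metadata,
                     var_equal = config$test_flavor == "student"), path)
    path
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$outputs <- outputs
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Row-stochastic confusion matrix with constant diagonal
#'
#' Off-diagonal mass is spread uniformly; handy for planting known rater
#' error rates in simulations.
#'
#' @param diagonal Probability of emitting the true class.
#' @return K x K matrix over [cell_legend()] classes.
#' @export
planted_confusion <- function(diagonal) {
  classes <- names(cell_legend())
  K <- length(classes)
  m <- matrix((1 - diagonal) / (K - 1), K, K,
              dimnames = list(classes, classes))
  diag(m) <- diagonal
  m
}
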