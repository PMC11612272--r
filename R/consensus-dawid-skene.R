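#' Bayesian consensus ground truth by Dawid-Skene EM
#'
#' Latent-class estimation of the true cell class at each consensus
#' location from multiple noisy labelers (pathologists plus the model
#' treated as one more labeler). Class prevalences and per-labeler
#' row-stochastic confusion matrices are estimated by EM to a MAP solution
#' under symmetric Dirichlet smoothing, `Dirichlet(1 + prior_strength)` on
#' every prevalence and confusion row. `"absent"` emissions (a labeler who
#' marked no point at the location) are non-informative: they are skipped
#' in the likelihood, separating detection from classification.
#' Initialization is the per-location majority vote, so the fit is
#' deterministic. On exact posterior ties the MAP class with the lowest
#' legend code wins.
#'
#' @param locations A `consensus_locations` tibble from
#'   [cluster_annotations()] (long: one row per location x labeler).
#' @param prior_strength Dirichlet smoothing strength (default 0.1).
#' @param tol Stop when the largest absolute change of any posterior
#'   probability falls below this (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return A `dawid_skene` object: `posterior` (locations x classes
#'   matrix), `map_class`, `prevalence`, `confusion` (named list of
#'   row-stochastic matrices per labeler), `log_posterior` trace,
#'   `converged`, `n_iter`.
#' @export
estimate_truth <- function(locations, prior_strength = 0.1, tol = 1e-6,
                           max_iter = 100L) {
  stopifnot(prior_strength >= 0, tol > 0, max_iter >= 1)
  classes <- names(cell_legend())
  K <- length(classes)
  lab <- locations[locations$label != "absent", , drop = FALSE]
  if (!nrow(lab)) stop("no labels at any location", call. = FALSE)
  bad <- setdiff(unique(lab$label), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  loc_ids <- sort(unique(locations$location_id))
  labelers <- sort(unique(locations$labeler_id))
  n <- length(loc_ids); J <- length(labelers)
  li <- match(lab$location_id, loc_ids)
  ji <- match(lab$labeler_id, labelers)
  ki <- match(lab$label, classes)
  alpha <- 1 + prior_strength

  # majority-vote initialization
  q <- matrix(0, n, K, dimnames = list(loc_ids, classes))
  votes <- matrix(0, n, K)
  for (r in seq_along(li)) votes[li[r], ki[r]] <- votes[li[r], ki[r]] + 1
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    q[i, top] <- 1 / length(top)
  }

  log_post <- numeric(0)
  converged <- FALSE
  theta <- NULL
  for (it in seq_len(max_iter)) {
    # M-step (MAP with Dirichlet(alpha) smoothing)
    prev <- colSums(q) + (alpha - 1)
    prev <- prev / sum(prev)
    theta <- lapply(seq_len(J), function(j) {
      sel <- ji == j
      cnt <- matrix(alpha - 1, K, K, dimnames = list(classes, classes))
      if (any(sel)) {
        for (r in which(sel)) cnt[, ki[r]] <- cnt[, ki[r]] + q[li[r], ]
      }
      cnt / rowSums(cnt)
    })
    # E-step
    logq <- matrix(rep(log(prev), each = n), n, K)
    for (r in seq_along(li)) {
      logq[li[r], ] <- logq[li[r], ] + log(theta[[ji[r]]][, ki[r]])
    }
    m <- apply(logq, 1L, max)
    w <- exp(logq - m)
    q_new <- w / rowSums(w)
    ll <- sum(m + log(rowSums(w)))
    lprior <- (alpha - 1) * (sum(log(prev)) +
                               sum(vapply(theta, function(th) sum(log(th)), 0)))
    log_post <- c(log_post, ll + lprior)
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  names(theta) <- labelers
  dimnames(q) <- list(loc_ids, classes)
  map_idx <- apply(q, 1L, function(p) which(p >= max(p) - 1e-12)[1])
  structure(
    list(
      posterior = q,
      map_class = stats::setNames(classes[map_idx], loc_ids),
      prevalence = stats::setNames(prev, classes),
      confusion = theta,
      log_posterior = log_post,
      converged = converged,
      n_iter = length(log_post),
      prior_strength = prior_strength,
      locations = locations
    ),
    class = "dawid_skene"
  )
}

#' @export
print.dawid_skene <- function(x, ...) {
  cat(sprintf("<dawid_skene> %d locations, %d labelers, %d iterations%s\n",
              nrow(x$posterior), length(x$confusion), x$n_iter,
              if (x$converged) " (converged)" else ""))
  cat("  prevalence:",
      paste(sprintf("%s %.2f", names(x$prevalence)[x$prevalence > 0.005],
                    x$prevalence[x$prevalence > 0.005]), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Dawid-Skene fit into per-labeler confusion rows
#'
#' @param x A `dawid_skene` fit.
#' @param ... Unused.
#' @return Tibble: `labeler_id`, `true_class`, `emitted_class`,
#'   `probability`.
#' @export
tidy.dawid_skene <- function(x, ...) {
  purrr::imap(x$confusion, function(th, j) {
    tibble::as_tibble(as.table(th), .name_repair = "minimal") |>
      stats::setNames(c("true_class", "emitted_class", "probability")) |>
      dplyr::mutate(labeler_id = j, .before = 1L)
  }) |> dplyr::bind_rows()
}

#' One-row summary of a Dawid-Skene fit
#'
#' @param x A `dawid_skene` fit.
#' @param ... Unused.
#' @return Tibble with location/labeler counts, iterations, final log
#'   posterior and convergence flag.
#' @export
glance.dawid_skene <- function(x, ...) {
  tibble::tibble(
    n_locations = nrow(x$posterior),
    n_labelers = length(x$confusion),
    n_iter = x$n_iter,
    log_posterior = x$log_posterior[length(x$log_posterior)],
    converged = x$converged
  )
}
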