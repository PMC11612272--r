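#' Encode modified Marsh grades on the ordinal scale
#'
#' Maps the six-level modified Marsh score to consecutive integers:
#' 0, 1, 2 -> 0, 1, 2 and the destructive sub-grades 3a, 3b, 3c -> 3, 4, 5.
#' Any strictly monotone encoding yields identical Spearman correlations;
#' this one is the canonical choice.
#'
#' @param grade Character vector of grades from [marsh_levels()].
#' @return Integer vector in 0..5.
#' @export
#' @examples
#' marsh_to_ordinal(c("0", "3a", "3c"))
marsh_to_ordinal <- function(grade) {
  idx <- match(as.character(grade), marsh_levels())
  if (any(is.na(idx) & !is.na(grade))) {
    stop("unknown Marsh grade(s): ",
         paste(unique(grade[is.na(idx) & !is.na(grade)]), collapse = ", "),
         call. = FALSE)
  }
  idx - 1L
}

#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (which applies the tie correction),
#' with a two-sided p-value from the t approximation on n - 2 degrees of
#' freedom. Pairs with a missing value are removed. A constant vector
#' yields an undefined (missing) correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Welch (or pooled Student) t-test from summary statistics
#'
#' Independent two-sample t-test computed from group means, standard
#' deviations and sizes, so published summary tables can be tested
#' directly. Default is Welch's unequal-variance form,
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom; `var_equal = TRUE` gives the pooled-variance
#' Student variant. Identical degenerate groups (both SDs zero, equal
#' means) yield an undefined test.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1 (`n1 >= 2`, `s1 >= 0`).
#' @param m2,s2,n2 Likewise for group 2; the SDs must not both be zero.
#' @param var_equal Use the pooled-variance Student form (default FALSE).
#' @return One-row tibble: `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`,
#'   `t`, `df`, `p_value`.
#' @export
#' @examples
#' welch_from_summary(0.33, 0.08, 52, 0.15, 0.07, 118)
welch_from_summary <- function(m1, s1, n1, m2, s2, n2, var_equal = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  out <- tibble::tibble(mean1 = m1, sd1 = s1, n1 = n1,
                        mean2 = m2, sd2 = s2, n2 = n2,
                        t = NA_real_, df = NA_real_, p_value = NA_real_)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) return(out)          # undefined t
    stop("both SDs are zero with unequal means: t is infinite",
         call. = FALSE)
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  out$t <- tstat; out$df <- df
  out$p_value <- 2 * stats::pt(-abs(tstat), df)
  out
}

#' Correlate every HIF with the ordinal Marsh grade
#'
#' Spearman rank correlation of each feature column against the
#' ordinal-encoded modified Marsh grade, pairwise-complete per feature,
#' sorted by `|rho|` descending (features with an undefined correlation are
#' kept but ranked last).
#'
#' @param hif_table Feature tibble from [extract_cohort_hifs()] (one row
#'   per slide, `slide_id` column).
#' @param metadata Either a tibble with `slide_id` and `grade` columns, or
#'   a vector of grades aligned with the rows of `hif_table`.
#' @return A `hif_correlations` tibble: `feature`, `rho`, `p_value`, `n`.
#' @export
correlate_features <- function(hif_table, metadata) {
  grades <- align_metadata(hif_table, metadata, "grade")
  ord <- marsh_to_ordinal(grades)
  feats <- setdiff(names(hif_table), "slide_id")
  out <- purrr::map(feats, function(f) {
    dplyr::bind_cols(tibble::tibble(feature = f),
                     spearman(hif_table[[f]], ord))
  }) |> dplyr::bind_rows()
  out <- out[order(is.na(out$rho), -abs(out$rho)), , drop = FALSE]
  structure(out, class = c("hif_correlations", class(out)))
}

#' Compare every HIF between normal and celiac groups
#'
#' Per-feature independent t-test on the raw per-slide values (Welch by
#' default), with group means and SDs laid out as in a summary table.
#' Features with fewer than two defined values in either group are
#' dropped. Raw p-values are reported (no multiple-testing correction, as
#' is conventional for descriptive feature tables); an optional
#' Benjamini-Hochberg column can be added.
#'
#' @param hif_table Feature tibble (one row per slide, `slide_id` column).
#' @param metadata Tibble with `slide_id` and `group` columns, or a vector
#'   of group labels aligned with rows. Exactly two groups required; the
#'   `"normal"` group (when present) is group 1.
#' @param var_equal Pooled-variance Student form instead of Welch.
#' @param adjust Add a `p_adjusted` Benjamini-Hochberg column (default
#'   FALSE).
#' @return A `hif_group_comparison` tibble: `feature`, `group1`, `mean1`,
#'   `sd1`, `n1`, `group2`, `mean2`, `sd2`, `n2`, `t`, `df`, `p_value`, in
#'   canonical feature order.
#' @export
compare_groups <- function(hif_table, metadata, var_equal = FALSE,
                           adjust = FALSE) {
  groups <- align_metadata(hif_table, metadata, "group")
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) != 2L) {
    stop("need exactly two groups, got: ", paste(lev, collapse = ", "),
         call. = FALSE)
  }
  if ("normal" %in% lev) lev <- c("normal", setdiff(lev, "normal"))
  feats <- setdiff(names(hif_table), "slide_id")
  canon <- hif_feature_names(extended = TRUE)
  feats <- c(intersect(canon, feats), setdiff(feats, canon))
  out <- purrr::map(feats, function(f) {
    v <- hif_table[[f]]
    x1 <- v[groups == lev[1] & is.finite(v)]
    x2 <- v[groups == lev[2] & is.finite(v)]
    if (length(x1) < 2L || length(x2) < 2L) return(NULL)
    res <- welch_from_summary(mean(x1), stats::sd(x1), length(x1),
                              mean(x2), stats::sd(x2), length(x2),
                              var_equal = var_equal)
    dplyr::bind_cols(
      tibble::tibble(feature = f, group1 = lev[1]),
      res[, c("mean1", "sd1", "n1")],
      tibble::tibble(group2 = lev[2]),
      res[, c("mean2", "sd2", "n2", "t", "df", "p_value")]
    )
  }) |> dplyr::bind_rows()
  if (adjust && nrow(out)) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  structure(out, class = c("hif_group_comparison", class(out)))
}

# metadata: tibble keyed by slide_id, or a vector aligned with rows
align_metadata <- function(hif_table, metadata, column) {
  if (is.data.frame(metadata)) {
    stopifnot(all(c("slide_id", column) %in% names(metadata)))
    out <- metadata[[column]][match(hif_table$slide_id, metadata$slide_id)]
    if (any(is.na(out))) {
      stop("metadata is missing ", column, " for some slides", call. = FALSE)
    }
    out
  } else {
    stopifnot(length(metadata) == nrow(hif_table))
    metadata
  }
}

#' Training/validation/test split fractions
#'
#' Percentage of slides in each split, to one decimal place, as reported
#' in dataset descriptions (e.g. 230 of 318 celiac slides -> 72.3%
#' training).
#'
#' @param n_train,n_validation,n_test Slide counts per split.
#' @return Tibble: `split`, `n`, `percent`.
#' @export
#' @examples
#' split_fractions(230, 60, 28)
split_fractions <- function(n_train, n_validation, n_test) {
  n <- c(train = n_train, validation = n_validation, test = n_test)
  stopifnot(all(n >= 0), sum(n) > 0)
  tibble::tibble(
    split = names(n),
    n = as.integer(n),
    percent = round(100 * n / sum(n), 1)
  )
}
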