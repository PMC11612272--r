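# Per-grade generator targets.
#
# Grade 0 anchors to the normal-duodenum column of the published feature
# table and grade 3c to the celiac column; intermediate grades are linear
# interpolations on the ordinal scale (the source reports only the two
# pooled columns, so the within-spectrum schedule is a modeling choice).

# (mean, sd) pairs at the two anchors; columns: normal mean/sd, celiac mean/sd
.anchor_table <- function() {
  tibble::tribble(
    ~quantity,              ~m0,     ~s0,    ~m1,     ~s1,
    "villous_frac",          0.33,    0.08,   0.15,    0.07,
    "crypt_frac",            0.24,    0.05,   0.27,    0.07,
    "crypt_frac_of_epith",   0.42,    0.10,   0.64,    0.14,
    "lp_frac",               0.31,    0.04,   0.47,    0.08,
    "iel_per_enterocyte",    0.20,    0.07,   0.31,    0.11,
    "iel_density_villous", 910.27,  303.15, 1446.27, 463.91,
    "plasma_prop_lp",        0.23,    0.05,   0.29,    0.10,
    "lymph_prop_lp",         0.27,    0.06,   0.19,    0.06,
    "neut_prop_mucosa",      0.03,    0.01,   0.05,    0.02,
    "eos_prop_mucosa",       0.02,    0.01,   0.03,    0.01
  )
}

# quantities the table does not report; fixed realistic values (see vignette)
.fixed_densities <- function() {
  list(
    crypt_enterocyte = c(mean = 4800, sd = 800),
    crypt_iel_0      = c(mean = 350,  sd = 150),
    crypt_iel_1      = c(mean = 900,  sd = 350),
    crypt_goblet     = c(mean = 480,  sd = 150),
    epith_other      = c(mean = 100,  sd = 50),
    goblet_per_enterocyte = 0.10
  )
}

# anchor params at t = 0 (normal) or t = 1 (celiac column)
.anchor_params <- function(t) {
  a <- .anchor_table()
  pick <- function(q) {
    r <- a[a$quantity == q, ]
    c(mean = (1 - t) * r$m0 + t * r$m1, sd = (1 - t) * r$s0 + t * r$s1)
  }
  fx <- .fixed_densities()

  villous <- pick("villous_frac")
  crypt   <- pick("crypt_frac")
  fce     <- pick("crypt_frac_of_epith")
  lp      <- pick("lp_frac")
  ratio   <- pick("iel_per_enterocyte")
  iel_v   <- pick("iel_density_villous")
  plasma  <- pick("plasma_prop_lp")
  lymph   <- pick("lymph_prop_lp")
  neutp   <- pick("neut_prop_mucosa")
  eosp    <- pick("eos_prop_mucosa")

  # implied total lamina-propria cell density: density / count-proportion,
  # averaged over the two classes the table reports both numbers for
  plasma_d <- c(2131.66, 2725.74); lymph_d <- c(2483.02, 1808.05)
  plasma_p <- c(0.23, 0.29);       lymph_p <- c(0.27, 0.19)
  tot0 <- mean(c(plasma_d[1] / plasma_p[1], lymph_d[1] / lymph_p[1]))
  tot1 <- mean(c(plasma_d[2] / plasma_p[2], lymph_d[2] / lymph_p[2]))
  lp_total <- c(mean = (1 - t) * tot0 + t * tot1,
                sd = (1 - t) * 1400 + t * 1700)

  ent_v  <- iel_v[["mean"]] / ratio[["mean"]]
  gob_v  <- ent_v * fx$goblet_per_enterocyte
  iel_c  <- (1 - t) * fx$crypt_iel_0 + t * fx$crypt_iel_1

  # total cell density per mm^2 of each epithelial compartment
  dv <- ent_v + iel_v[["mean"]] + gob_v + fx$epith_other[["mean"]]
  dc <- fx$crypt_enterocyte[["mean"]] + iel_c[["mean"]] +
    fx$crypt_goblet[["mean"]] + fx$epith_other[["mean"]]
  # compartment fractions of mucosa at the anchor means
  v <- villous[["mean"]]
  cfrac <- crypt[["mean"]]
  l <- lp[["mean"]]
  # expected cells per mm^2 of mucosa -> lamina-propria granulocyte
  # densities that hit the mucosa-wide count-proportion targets
  total_mucosa <- v * dv + cfrac * dc + l * lp_total[["mean"]]
  neut <- c(mean = neutp[["mean"]] * total_mucosa / l,
            sd = neutp[["sd"]] * total_mucosa / l)
  eos  <- c(mean = eosp[["mean"]] * total_mucosa / l,
            sd = eosp[["sd"]] * total_mucosa / l)

  list(
    villous_frac = villous, crypt_frac = crypt, crypt_frac_of_epith = fce,
    lp_frac = lp, lp_villous_coupling = 0.4,
    iel_per_enterocyte = ratio, iel_density_villous = iel_v,
    goblet_density_villous = c(mean = gob_v, sd = 0.25 * gob_v),
    other_density_epith = fx$epith_other,
    enterocyte_density_crypt = fx$crypt_enterocyte,
    iel_density_crypt = iel_c,
    goblet_density_crypt = fx$crypt_goblet,
    lp_total_density = lp_total,
    plasma_prop_lp = plasma, lymph_prop_lp = lymph,
    neut_density_lp = neut, eos_density_lp = eos,
    artifact_fraction = 0.02
  )
}

#' Generator targets for one modified Marsh grade
#'
#' Returns the per-grade statistical targets the synthetic-histology
#' generator draws each slide from: compartment area fractions of mucosa
#' (villous epithelium, lamina propria, and crypt epithelium via its share
#' of all epithelium), the IEL-per-enterocyte ratio, per-compartment cell
#' densities in cells/mm^2, and the artifact coverage fraction. Grade 0
#' anchors to published normal-duodenum means/SDs and grade 3c to the
#' celiac column; intermediate grades interpolate linearly on the ordinal
#' scale.
#'
#' @param grade One of [marsh_levels()].
#' @param ... Named overrides, each a `c(mean =, sd =)` pair (or a scalar
#'   for `artifact_fraction`) replacing the default of the same name.
#' @return A `grade_params` list. `(mean, sd)` entries:
#'   `villous_frac`, `crypt_frac`, `lp_frac` (fractions of mucosa; the
#'   generator draws these, with lamina propria negatively coupled to the
#'   villous draw via `lp_villous_coupling` as in real mucosa),
#'   `crypt_frac_of_epith` (the implied crypt share of all epithelium,
#'   kept as a documented calibration target),
#'   `iel_per_enterocyte` (ratio), `*_density_*` and `lp_total_density`
#'   (cells/mm^2), `plasma_prop_lp`, `lymph_prop_lp` (count proportions);
#'   plus scalar `artifact_fraction`.
#' @export
#' @examples
#' grade_params("0")$villous_frac
#' grade_params("3c")$villous_frac
grade_params <- function(grade, ...) {
  grade <- as.character(grade)
  ord <- marsh_to_ordinal(grade)
  p <- .anchor_params(ord / 5)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown grade_params field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p$grade <- grade
  validate_grade_params(structure(p, class = "grade_params"))
}

validate_grade_params <- function(p) {
  pairs <- p[vapply(p, function(x) is.numeric(x) && length(x) == 2L, TRUE)]
  for (nm in names(pairs)) {
    x <- pairs[[nm]]
    if (x[["mean"]] < 0 || x[["sd"]] < 0) {
      stop("grade_params$", nm, ": mean and sd must be >= 0", call. = FALSE)
    }
    if (grepl("frac|prop", nm) && x[["mean"]] > 1) {
      stop("grade_params$", nm, ": fraction mean must be <= 1", call. = FALSE)
    }
  }
  af <- p$artifact_fraction
  if (!is.numeric(af) || length(af) != 1L || af < 0 || af > 1) {
    stop("artifact_fraction must be a scalar in [0, 1]", call. = FALSE)
  }
  p
}

#' @export
print.grade_params <- function(x, ...) {
  cat(sprintf("<grade_params> Marsh %s\n", x$grade))
  cat(sprintf("  villous/mucosa %.3f (%.3f); crypt/epithelium %.3f (%.3f); LP/mucosa %.3f (%.3f)\n",
              x$villous_frac[["mean"]], x$villous_frac[["sd"]],
              x$crypt_frac_of_epith[["mean"]], x$crypt_frac_of_epith[["sd"]],
              x$lp_frac[["mean"]], x$lp_frac[["sd"]]))
  cat(sprintf("  IEL/enterocyte %.3f (%.3f); IEL density (villous) %.0f (%.0f) /mm^2\n",
              x$iel_per_enterocyte[["mean"]], x$iel_per_enterocyte[["sd"]],
              x$iel_density_villous[["mean"]], x$iel_density_villous[["sd"]]))
  invisible(x)
}
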