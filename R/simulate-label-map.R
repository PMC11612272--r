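#' Simulate a graded duodenal-mucosa tissue label map
#'
#' Renders a synthetic single-channel tissue raster with the compartment
#' structure of an oriented duodenal biopsy: finger-like villi (epithelial
#' rim around a lamina-propria core) above a crypt band (crypt epithelium
#' with lumina separated by lamina-propria septa), a free lamina-propria
#' band, muscularis mucosae, and an other-tissue base containing blood
#' vessels, under luminal background. Per-slide compartment area fractions
#' are drawn from the grade's targets ([grade_params()]); after rendering,
#' an exact pixel-count correction reassigns a small number of pixels so
#' each mucosal class area equals its drawn target exactly, which keeps the
#' generator unbiased with respect to its calibration targets. Grade acts
#' through the targets: higher grades shrink villi and expand crypts and
#' lamina propria.
#'
#' @param grade Modified Marsh grade, one of [marsh_levels()].
#' @param params A [grade_params()] object; defaults to the grade's.
#' @param shape Raster dimensions `c(rows, cols)` in pixels, each >= 64.
#' @param mpp Microns per pixel.
#' @param seed Integer seed; identical inputs give bit-identical rasters.
#' @return A [label_map()].
#' @export
#' @examples
#' m <- simulate_label_map("0", shape = c(96, 96), seed = 1)
#' class_pixel_counts(m)
simulate_label_map <- function(grade, params = grade_params(grade),
                               shape = c(512, 512), mpp = 0.25, seed = 1L) {
  stopifnot(length(shape) == 2L)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (H < 64L || W < 64L) {
    stop("degenerate geometry: shape must be at least 64 x 64 px to place ",
         "a villus and a crypt", call. = FALSE)
  }
  validate_grade_params(params)
  legend <- tissue_legend()

  withr::with_seed(seed, {
    # per-slide compartment targets (fractions of mucosa); lamina propria
    # is negatively coupled to the villous draw (blunting expands LP), and
    # only the rare incoherent tail (sum > 0.985) is rescaled, keeping the
    # draws unbiased for calibration purposes
    v  <- rnorm_clamped(1, params$villous_frac, 0, 0.85)
    cf <- rnorm_clamped(1, params$crypt_frac, 0, 0.85)
    beta <- params$lp_villous_coupling %||% 0.4
    lp_resid_sd <- sqrt(max(params$lp_frac[["sd"]]^2 -
                              (beta * params$villous_frac[["sd"]])^2, 0))
    lp_mean <- params$lp_frac[["mean"]] +
      beta * (params$villous_frac[["mean"]] - v)
    lp <- rnorm_clamped(1, c(mean = lp_mean, sd = lp_resid_sd), 0.02, 0.85)
    tot <- v + cf + lp
    if (tot > 0.985) {
      sc <- 0.985 / tot
      v <- v * sc; cf <- cf * sc; lp <- lp * sc; tot <- 0.985
    }
    rest  <- 1 - tot
    lumen <- 0.6 * rest
    mmf   <- 0.4 * rest

    mucosa_px <- round(0.72 * H * W)
    B <- c(
      villous_epithelium = round(v * mucosa_px),
      crypt_epithelium   = round(cf * mucosa_px),
      crypt_lumen        = round(lumen * mucosa_px),
      lamina_propria     = round(lp * mucosa_px),
      muscularis_mucosa  = 0L
    )
    B["muscularis_mucosa"] <- max(0L, mucosa_px - sum(B))

    M <- matrix(legend[["background"]], H, W)

    # other-tissue base with blood vessels
    h_ot <- max(2L, round(0.06 * H))
    ot_rows <- (H - h_ot + 1L):H
    M[ot_rows, ] <- legend[["other_tissue"]]
    n_bv <- max(1L, round(H * W / 30000))
    r_bv <- max(1, round(0.012 * min(H, W)))
    for (k in seq_len(n_bv)) {
      cy <- stats::runif(1, H - h_ot + r_bv, H - r_bv)
      cx <- stats::runif(1, 1 + r_bv, W - r_bv)
      M[disk_indices(cy, cx, r_bv, H, W)] <- legend[["blood_vessel"]]
    }

    # muscularis mucosae band
    h_mm <- max(1L, ceiling(B[["muscularis_mucosa"]] / W))
    mm_top <- H - h_ot - h_mm + 1L
    M[mm_top:(H - h_ot), ] <- legend[["muscularis_mucosa"]]

    # crypt band: periodic crypt units with lumina, lamina-propria septa
    crypt_content <- B[["crypt_epithelium"]] + B[["crypt_lumen"]]
    h_cb <- if (crypt_content > 0) ceiling(crypt_content / (W * 0.85)) else 0L
    cb_bottom <- mm_top - 1L
    cb_top <- cb_bottom - h_cb + 1L
    if (h_cb > 0L && cb_top >= 1L) {
      p_c <- max(8L, round(min(H, W) / 12))
      w_c <- max(4L, round(0.85 * p_c))
      lf  <- if (crypt_content > 0) B[["crypt_lumen"]] / crypt_content else 0
      inner_rows <- if (h_cb > 4L) (cb_top + 2L):(cb_bottom - 2L) else integer()
      w_l <- if (length(inner_rows)) {
        round(w_c * lf * h_cb / length(inner_rows))
      } else 0L
      for (x0 in seq(1L, W, by = p_c)) {
        xe <- min(W, x0 + w_c - 1L)
        M[cb_top:cb_bottom, x0:xe] <- legend[["crypt_epithelium"]]
        if (w_l > 0L && length(inner_rows)) {
          lx0 <- x0 + max(1L, (w_c - w_l) %/% 2L)
          lxe <- min(xe - 1L, lx0 + w_l - 1L)
          if (lxe >= lx0) M[inner_rows, lx0:lxe] <- legend[["crypt_lumen"]]
        }
        if (xe < W) {
          sx <- min(W, x0 + p_c - 1L)
          if (sx > xe) M[cb_top:cb_bottom, (xe + 1L):sx] <- legend[["lamina_propria"]]
        }
      }
    } else {
      cb_top <- mm_top                    # empty crypt band
    }

    # free lamina-propria band (budget left after septa and villus cores)
    lp_placed <- sum(M == legend[["lamina_propria"]])
    f_rim <- 0.75
    lp_in_villi <- B[["villous_epithelium"]] * (1 - f_rim) / f_rim
    lp_left <- max(0, B[["lamina_propria"]] - lp_placed - lp_in_villi)
    h_lp <- ceiling(lp_left / W)
    lp_bottom <- cb_top - 1L
    lp_top <- max(1L, lp_bottom - h_lp + 1L)
    if (h_lp > 0L && lp_bottom >= lp_top) {
      M[lp_top:lp_bottom, ] <- legend[["lamina_propria"]]
    } else lp_top <- cb_top

    # villus zone: fingers with epithelial rim and lamina-propria core
    if (B[["villous_epithelium"]] > 0L) {
      w_share <- 0.7
      h_vz <- ceiling(B[["villous_epithelium"]] / (f_rim * w_share * W))
      vz_bottom <- lp_top - 1L
      min_bg <- max(1L, round(0.03 * H))
      vz_top <- max(min_bg + 1L, vz_bottom - h_vz + 1L)
      if (vz_bottom > vz_top) {
        zone_h <- vz_bottom - vz_top + 1L
        p_v <- max(10L, round(min(H, W) / 8))
        w_v <- max(4L, round(w_share * p_v))
        t_r <- max(1L, round(0.375 * w_v))
        for (x0 in seq(1L, W, by = p_v)) {
          xe <- min(W, x0 + w_v - 1L)
          h_k <- min(zone_h, max(4L, round(zone_h * stats::runif(1, 0.8, 1.2))))
          top_k <- vz_bottom - h_k + 1L
          M[top_k:vz_bottom, x0:xe] <- legend[["villous_epithelium"]]
          core_x0 <- x0 + t_r; core_xe <- xe - t_r
          core_top <- top_k + t_r
          if (core_xe >= core_x0 && vz_bottom >= core_top) {
            M[core_top:vz_bottom, core_x0:core_xe] <- legend[["lamina_propria"]]
          }
        }
      }
    }

    # exact-count correction: make each mucosal class hit its drawn budget
    region <- which(row(M) <= H - h_ot)       # all rows above the base band
    M <- correct_counts(M, B, legend, region)

    label_map(M, legend, mpp)
  })
}

# Reassign pixels inside `region` so each budgeted class's count equals its
# budget exactly; surplus pixels (and background, the residual class) form
# the pool that deficits draw from, uniformly at random.
correct_counts <- function(M, budgets, legend, region) {
  vals <- M[region]
  pool <- integer()
  for (cls in names(budgets)) {
    code <- legend[[cls]]
    idx <- region[vals == code]
    surplus <- length(idx) - budgets[[cls]]
    if (surplus > 0L) {
      drop <- if (surplus >= length(idx)) idx else sample(idx, surplus)
      pool <- c(pool, drop)
    }
  }
  deficits <- vapply(names(budgets), function(cls) {
    max(0, budgets[[cls]] - sum(vals == legend[[cls]]))
  }, numeric(1))
  need <- sum(deficits)
  if (need > length(pool)) {
    bg <- region[vals == legend[["background"]]]
    bg <- setdiff(bg, pool)
    extra <- need - length(pool)
    if (extra > length(bg)) extra <- length(bg)
    pool <- c(pool, if (extra > 0L) sample(bg, extra) else integer())
  }
  pool <- sample(pool)
  pos <- 1L
  for (cls in names(budgets)) {
    d <- deficits[[cls]]
    if (d > 0L && pos <= length(pool)) {
      take <- pool[pos:min(length(pool), pos + d - 1L)]
      M[take] <- legend[[cls]]
      pos <- pos + length(take)
    }
  }
  if (pos <= length(pool)) M[pool[pos:length(pool)]] <- legend[["background"]]
  M
}
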