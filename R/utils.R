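# deterministic child seed (< 2^31) for per-slide / per-stage RNG streams
derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(i) * 9973) %% 2147483647) + 1L
}

# normal draw clamped to [lower, upper]; sd = 0 gives the mean exactly
rnorm_clamped <- function(n, pair, lower = 0, upper = Inf) {
  m <- pair[["mean"]]; s <- pair[["sd"]]
  if (s == 0) return(rep(min(max(m, lower), upper), n))
  pmin(pmax(stats::rnorm(n, m, s), lower), upper)
}

# linear row/col indices of a filled disk, clipped to the raster
disk_indices <- function(cy, cx, r, H, W) {
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= r^2
  g <- g[keep, , drop = FALSE]
  (g$col - 1L) * H + g$row
}

`%||%` <- function(a, b) if (is.null(a)) b else a
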