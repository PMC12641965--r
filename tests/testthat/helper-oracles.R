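# Independent brute-force GLCM entropy: per-pixel pair enumeration with an
# explicit co-occurrence matrix. Deliberately loop-based and separate from
# the package's vectorized implementation.
brute_glcm_entropy <- function(img, mask = NULL, levels = 256L, dist = 1L,
                               directions = rbind(c(0L, 1L), c(1L, 0L),
                                                  c(1L, 1L), c(1L, -1L)),
                               symmetric = TRUE) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- img[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  if (diff(rng) == 0) {
    q[mask] <- 0L
  } else {
    q[mask] <- pmin(as.integer(floor((v - rng[1]) / diff(rng) * levels)),
                    levels - 1L)
  }
  C <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img))) {
      if (!mask[r, cc]) next
      for (k in seq_len(nrow(directions))) {
        r2 <- r + directions[k, 1] * dist
        c2 <- cc + directions[k, 2] * dist
        if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
        if (!mask[r2, c2]) next
        i <- q[r, cc] + 1L; j <- q[r2, c2] + 1L
        C[i, j] <- C[i, j] + 1
        if (symmetric) C[j, i] <- C[j, i] + 1
      }
    }
  }
  if (sum(C) == 0) return(NA_real_)
  p <- C[C > 0] / sum(C)
  -sum(p * log2(p))
}

# small default config for fast tests
quick_cfg <- function(...) synth_config(seed = 42, ...)

# rasterized disk helper for mask oracles
raster_disk <- function(n, cx, cy, r) {
  x <- matrix(rep(seq_len(n), n), n)
  y <- matrix(rep(seq_len(n), each = n), n)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# wrap matrices into a minimal record
mat_record <- function(..., pixel_size_um = 1) {
  cell_record("r1", channels = list(...), pixel_size_um = pixel_size_um)
}
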