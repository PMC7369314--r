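# Independent brute-force oracles and small fixtures shared across tests.

# Disk mask built independently of dgquant::disk_kernel.
oracle_disk <- function(r) {
  off <- -r:r
  outer(off, off, function(dx, dy) dx^2 + dy^2 <= r^2)
}

# Brute-force flat erosion/dilation: per-pixel window extraction, min/max over
# the structuring element, pixels outside the image ignored.
bf_filter <- function(img, mask, fun) {
  r <- (nrow(mask) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    ri <- max(1L, i - r):min(h, i + r)
    for (j in seq_len(w)) {
      rj <- max(1L, j - r):min(w, j + r)
      msub <- mask[ri - i + r + 1L, rj - j + r + 1L, drop = FALSE]
      out[i, j] <- fun(img[ri, rj, drop = FALSE][msub])
    }
  }
  out
}

bf_opening <- function(img, r) {
  mask <- oracle_disk(r)
  bf_filter(bf_filter(img, mask, min), mask, max)
}

# Small artifact-free image spec for fast unit tests.
quick_spec <- function(n_cells, seed, width = 320L, height = 320L, ...) {
  image_spec(width_px = width, height_px = height, n_cells = n_cells,
             n_small_artifacts = 0L, n_large_artifacts = 0L, seed = seed, ...)
}

# A filled disk of the given value pasted onto a matrix (hard-edged spot).
paste_disk <- function(img, cx, cy, r, value) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <- value
  }
  img
}
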