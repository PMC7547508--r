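# Low-level image operations shared by the filters, the evaluation metrics and
# the synthetic-scene generator. All functions operate on plain numeric
# matrices (H x W, row 1 = top) or H x W x C arrays, use symmetric (mirrored,
# edge-repeating) border padding, and are deterministic.

# Mirror-pad a matrix by k pixels on every side. k must be < dim.
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  if (k >= h || k >= w)
    abort(sprintf("padding %d too large for a %d x %d image", k, h, w), "bad_dims")
  ri <- c(k:1, 1:h, h:(h - k + 1))
  ci <- c(k:1, 1:w, w:(w - k + 1))
  m[ri, ci, drop = FALSE]
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with mirrored borders. Works on a matrix or on each
# channel/band of a 3-D array. radius defaults to ceiling(3*sigma).
gaussian_blur <- function(x, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(x)
  if (length(dim(x)) == 3L) {
    out <- x
    for (c in seq_len(dim(x)[3])) out[, , c] <- gaussian_blur(x[, , c], sigma, radius)
    return(out)
  }
  k <- gaussian_kernel1d(sigma, radius)
  p <- pad_reflect(x, radius)
  h <- nrow(x); w <- ncol(x)
  # rows pass
  acc <- matrix(0, h, w + 2L * radius)
  for (d in -radius:radius)
    acc <- acc + k[d + radius + 1L] * p[(1L + radius + d):(h + radius + d), , drop = FALSE]
  # cols pass
  out <- matrix(0, h, w)
  for (d in -radius:radius)
    out <- out + k[d + radius + 1L] * acc[, (1L + radius + d):(w + radius + d), drop = FALSE]
  out
}

# (2r+1) x (2r+1) box mean with mirrored borders, via 2-D cumulative sums.
box_mean <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  p <- pad_reflect(m, r)
  # integral image with a zero first row/col
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  n <- 2L * r + 1L
  i1 <- 1L:h; j1 <- 1L:w
  (s[i1 + n, j1 + n] - s[i1, j1 + n] - s[i1 + n, j1] + s[i1, j1]) / (n * n)
}

# Bilinear resampling to (h2, w2), pixel-centred mapping, clamped at borders.
bilinear_resample <- function(m, h2, w2) {
  if (length(dim(m)) == 3L) {
    out <- array(0, c(h2, w2, dim(m)[3]))
    for (c in seq_len(dim(m)[3])) out[, , c] <- bilinear_resample(m[, , c], h2, w2)
    return(out)
  }
  h <- nrow(m); w <- ncol(m)
  sy <- (seq_len(h2) - 0.5) * h / h2 + 0.5   # source row coordinate (1-based centres)
  sx <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  y0 <- pmin(pmax(floor(sy), 1L), h); y1 <- pmin(y0 + 1L, h); fy <- pmin(pmax(sy - y0, 0), 1)
  x0 <- pmin(pmax(floor(sx), 1L), w); x1 <- pmin(x0 + 1L, w); fx <- pmin(pmax(sx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, h2, w2); wx <- matrix(fx, h2, w2, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

# Sub-pixel translation by (dy, dx) pixels (positive = down/right), bilinear,
# mirrored borders. Used for guidance misregistration.
shift_bilinear <- function(m, dy, dx) {
  if (length(dim(m)) == 3L) {
    out <- m
    for (c in seq_len(dim(m)[3])) out[, , c] <- shift_bilinear(m[, , c], dy, dx)
    return(out)
  }
  k <- ceiling(max(abs(dy), abs(dx))) + 1L
  p <- pad_reflect(m, k)
  h <- nrow(m); w <- ncol(m)
  y <- seq_len(h) + k - dy; x <- seq_len(w) + k - dx
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  a <- p[y0, x0, drop = FALSE]; b <- p[y0, x0 + 1L, drop = FALSE]
  c_ <- p[y0 + 1L, x0, drop = FALSE]; d <- p[y0 + 1L, x0 + 1L, drop = FALSE]
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

# Rec. 601 luma of an H x W x 3 array (or pass a matrix through unchanged).
luminance <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    abort("expected an H x W x 3 array or a matrix", "bad_dims")
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

# 8-connected component labelling of a logical mask (two-pass union-find).
# Returns an integer matrix, 0 = background, components numbered 1..n in
# raster-scan order of first appearance.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1L && lab[i - 1L, j] > 0L) nb <- c(nb, lab[i - 1L, j])
    if (j > 1L) {
      if (lab[i, j - 1L] > 0L) nb <- c(nb, lab[i, j - 1L])
      if (lab[i - 1L, j - 1L] > 0L && i > 1L) nb <- c(nb, lab[i - 1L, j - 1L])
      if (i < h && lab[i + 1L, j - 1L] > 0L) nb <- c(nb, lab[i + 1L, j - 1L])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      r0 <- min(roots)
      lab[i, j] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  nz <- lab > 0L
  ids <- roots[lab[nz]]
  u <- unique(ids)                    # order of first appearance in the scan
  remap <- integer(nxt)
  remap[u] <- seq_along(u)
  lab[nz] <- remap[ids]
  lab
}
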