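# Independent brute-force oracles for the edge-preserving filters. These
# implement the filter definitions literally (double loops over pixel pairs,
# per-window least squares) and share nothing with the package's vectorized /
# integral-image implementations beyond the border convention.

pad_mirror <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  m[c(k:1, 1:h, h:(h - k + 1)), c(k:1, 1:w, w:(w - k + 1)), drop = FALSE]
}

# literal joint bilateral filter: per-pixel double loop over the truncation
# window, spatial weight exp(-||i-j|| / sigma_d^2) (or squared form), range
# weight exp(-|I_i - I_j|^2 / sigma_r^2), normalized by K_i
jbf_oracle <- function(p, g, sigma_d, sigma_r, spatial_squared = FALSE) {
  half <- as.integer(ceiling(3 * sigma_d))
  h <- nrow(p); w <- ncol(p)
  if (is.matrix(g)) g <- array(g, c(dim(g), 1L))
  nch <- dim(g)[3]
  pp <- pad_mirror(p, half)
  gp <- array(0, c(h + 2 * half, w + 2 * half, nch))
  for (c in seq_len(nch)) gp[, , c] <- pad_mirror(g[, , c], half)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    num <- 0; den <- 0
    for (dy in -half:half) for (dx in -half:half) {
      d2 <- dy^2 + dx^2
      sw <- exp(-(if (spatial_squared) d2 else sqrt(d2)) / sigma_d^2)
      di2 <- 0
      for (c in seq_len(nch))
        di2 <- di2 + (gp[i + half, j + half, c] - gp[i + half + dy, j + half + dx, c])^2
      wt <- sw * exp(-di2 / sigma_r^2)
      num <- num + wt * pp[i + half + dy, j + half + dx]
      den <- den + wt
    }
    out[i, j] <- num / den
  }
  out
}

# literal (2r+1) box mean with mirrored borders
naive_box <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  p <- pad_mirror(m, r)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- mean(p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# literal guided filter: per-window regularized least squares solved through
# the 2x2 normal equations of the cost sum((a I + b - P)^2 + eps a^2) over the
# window, then averaging (a, b) over all windows containing each pixel
gf_oracle <- function(p, g, r, eps) {
  h <- nrow(p); w <- ncol(p)
  gp <- pad_mirror(g, r); pp <- pad_mirror(p, r)
  a <- matrix(0, h, w); b <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    I <- as.vector(gp[i:(i + 2 * r), j:(j + 2 * r)])
    P <- as.vector(pp[i:(i + 2 * r), j:(j + 2 * r)])
    n <- length(I)
    M <- rbind(c(sum(I * I) + n * eps, sum(I)), c(sum(I), n))
    if (abs(det(M)) < 1e-300) { a[i, j] <- 0; b[i, j] <- mean(P) }
    else { ab <- solve(M, c(sum(I * P), sum(P))); a[i, j] <- ab[1]; b[i, j] <- ab[2] }
  }
  naive_box(a, r) * g + naive_box(b, r)
}

# kernel perceptron with the Gaussian RBF kernel exp(-||x-y||^2 / gamma^2):
# an independent check that a feature set is G-RBF-separable
kernel_perceptron_acc <- function(x, y, gamma, epochs = 200) {
  n <- nrow(x)
  K <- exp(-as.matrix(dist(x))^2 / gamma^2)
  alpha <- numeric(n)
  ys <- ifelse(y == y[1], 1, -1)
  for (e in seq_len(epochs)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      f <- sum(alpha * ys * K[, i])
      if (sign(f + 1e-12) != ys[i]) { alpha[i] <- alpha[i] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  pred <- sign(colSums(alpha * ys * K))
  mean(pred == ys)
}
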