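# Guidance-image construction and the two edge-preserving filters used to
# regularize the per-class probability maps: the joint bilateral filter (JBF)
# and the guided filter (GF).
#
# Both filters use mirrored-border padding, so the filtered value at every
# pixel is a weighted average over a full window; this avoids darkening at the
# image border.

#' PCA false-colour guidance image
#'
#' Projects the band space of a cube onto its first three principal components
#' and returns the score maps as a 3-channel image, each channel independently
#' min-max rescaled to \[0, 1\]. The sign of each component is fixed by making
#' the largest-magnitude entry of its loading vector positive, so the output
#' is deterministic.
#'
#' @param cube a [hyperspectral_cube()] with at least 3 bands.
#' @return a [guidance_image()] with provenance `"pca_false_color"`.
#' @export
pca_false_color <- function(cube) {
  d <- dim(cube$values)
  if (d[3] < 3L) abort("PCA false colour needs at least 3 bands", "bad_dims")
  x <- cube_feature_matrix(cube)
  if (any(!is.finite(x))) abort("cube contains non-finite values", "bad_value")
  if (all(apply(x, 2L, stats::sd) == 0)) abort("cube has zero variance", "bad_value")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1:3, drop = FALSE]
  for (c in 1:3) {                       # deterministic sign convention
    j <- which.max(abs(rot[, c]))
    if (rot[j, c] < 0) rot[, c] <- -rot[, c]
  }
  scores <- sweep(x, 2L, pc$center) %*% rot
  out <- array(0, c(d[1], d[2], 3L))
  for (c in 1:3) {
    s <- scores[, c]
    rng <- range(s)
    out[, , c] <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else 0.5
  }
  guidance_image(out, provenance = "pca_false_color")
}

#' Resample a guidance image to the cube grid
#'
#' Bilinear resampling of a (typically higher-resolution) RGB image to the
#' spatial grid of the cube it will guide; values are clipped to \[0, 1\].
#'
#' @param rgb a [guidance_image()].
#' @param target_shape `c(H, W)` of the cube.
#' @return a [guidance_image()] of shape `target_shape`.
#' @export
resample_guidance <- function(rgb, target_shape) {
  if (any(target_shape < 1L)) abort("target shape must be positive", "bad_dims")
  v <- bilinear_resample(rgb$values, target_shape[1], target_shape[2])
  guidance_image(clip01(v), provenance = rgb$provenance)
}

guidance_values <- function(guidance) {
  if (inherits(guidance, "guidance_image")) guidance$values else guidance
}

#' Joint bilateral filter
#'
#' Filters a scalar map `p` with weights computed from a guidance image:
#' the spatial kernel is `exp(-||i-j|| / sigma_d^2)` and the range kernel
#' `exp(-|I_i-I_j|^2 / sigma_r^2)`, normalized per pixel so the weights sum
#' to 1. For a 3-channel guidance the range distance is the squared Euclidean
#' norm over channels. Weights are evaluated in a square window of half-width
#' `ceiling(3 * sigma_d)` with mirrored borders.
#'
#' The spatial kernel above uses the *unsquared* distance `||i-j||`; set
#' `spatial_squared = TRUE` for the conventional Gaussian form
#' `exp(-||i-j||^2 / sigma_d^2)`.
#'
#' @param p numeric H x W matrix (e.g. one class-probability map).
#' @param guidance a [guidance_image()] or an H x W (x3) array in \[0, 1\].
#' @param sigma_d spatial kernel width (pixels), > 0.
#' @param sigma_r range kernel width (guidance-intensity units), > 0.
#' @param spatial_squared use the conventional squared-distance spatial kernel.
#' @return filtered H x W matrix; a convex combination of the values of `p`.
#' @export
joint_bilateral_filter <- function(p, guidance, sigma_d, sigma_r,
                                   spatial_squared = FALSE) {
  g <- guidance_values(guidance)
  gd <- dim(g)
  if (!is.matrix(p)) abort("p must be a matrix", "bad_dims")
  if (any(gd[1:2] != dim(p))) abort("guidance and p shapes differ", "bad_dims")
  if (sigma_d <= 0 || sigma_r <= 0) abort("sigma_d and sigma_r must be > 0", "bad_value")
  half <- as.integer(ceiling(3 * sigma_d))
  h <- nrow(p); w <- ncol(p)
  pp <- pad_reflect(p, half)
  if (is.matrix(g)) g <- array(g, c(dim(g), 1L))
  nch <- dim(g)[3]
  gp <- array(0, c(h + 2L * half, w + 2L * half, nch))
  for (c in seq_len(nch)) gp[, , c] <- pad_reflect(g[, , c], half)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  ri <- (1L + half):(h + half); ci <- (1L + half):(w + half)
  for (dy in -half:half) for (dx in -half:half) {
    dist2 <- dy * dy + dx * dx
    sw <- exp(-(if (spatial_squared) dist2 else sqrt(dist2)) / sigma_d^2)
    dI2 <- 0
    for (c in seq_len(nch))
      dI2 <- dI2 + (gp[ri, ci, c] - gp[ri + dy, ci + dx, c])^2
    wgt <- sw * exp(-dI2 / sigma_r^2)
    num <- num + wgt * pp[ri + dy, ci + dx]
    den <- den + wgt
  }
  num / den
}

#' Guided filter
#'
#' Filters a scalar map `p` through a local linear model of a single-channel
#' guidance image `I`: in every `(2r+1) x (2r+1)` window `w_k` the coefficients
#' `a_k = cov_k(I, P) / (var_k(I) + epsilon)` and `b_k = mean_k(P) - a_k
#' mean_k(I)` minimize the regularized least-squares cost, and the output at
#' pixel `i` averages `a_k I_i + b_k` over all windows containing `i`. Window
#' statistics are computed in O(1) per pixel via integral images; borders are
#' mirrored.
#'
#' @param p numeric H x W matrix.
#' @param guidance single-channel H x W matrix in \[0, 1\] (reduce RGB guidance
#'   to luminance first; see [filter_stack()]).
#' @param r window radius, integer >= 1.
#' @param epsilon regularizer, >= 0 (0 gives the exact self-guidance identity).
#' @return filtered H x W matrix.
#' @export
guided_filter <- function(p, guidance, r, epsilon) {
  g <- guidance_values(guidance)
  if (!is.matrix(g)) abort("guided filter needs a single-channel guidance", "bad_dims")
  if (!is.matrix(p) || any(dim(g) != dim(p))) abort("guidance and p shapes differ", "bad_dims")
  if (r < 1) abort("window radius r must be >= 1", "bad_value")
  if (epsilon < 0) abort("epsilon must be >= 0", "bad_value")
  r <- as.integer(r)
  mu <- box_mean(g, r)
  mp <- box_mean(p, r)
  var_g <- box_mean(g * g, r) - mu^2
  cov_gp <- box_mean(g * p, r) - mu * mp
  den <- var_g + epsilon
  a <- ifelse(den > 0, cov_gp / den, 0)
  b <- mp - a * mu
  box_mean(a, r) * g + box_mean(b, r)
}

#' Filter every layer of a probability stack
#'
#' Applies the chosen edge-preserving filter independently to each of the K
#' class-probability maps with the same guidance and parameters. The JBF uses
#' the full (possibly 3-channel) guidance; the GF, whose local linear model is
#' scalar, uses its luminance. The filtered stack is clipped to \[0, 1\] but
#' deliberately *not* renormalized: the max-probability fusion is invariant to
#' per-pixel positive rescaling.
#'
#' @param stack a [probability_stack()].
#' @param guidance a [guidance_image()].
#' @param method `"jbf"` or `"gf"`.
#' @param params list of filter parameters: `sigma_d`, `sigma_r` (and
#'   optionally `spatial_squared`) for the JBF; `r`, `epsilon` for the GF.
#' @return a filtered [probability_stack()].
#' @export
filter_stack <- function(stack, guidance, method = c("jbf", "gf"), params = list()) {
  method <- match.arg(method)
  if (dim(stack$values)[3] < 2L) abort("stack must have K >= 2 layers", "bad_dims")
  g <- guidance_values(guidance)
  out <- stack$values
  if (method == "jbf") {
    for (k in seq_len(dim(out)[3]))
      out[, , k] <- joint_bilateral_filter(
        stack$values[, , k], g,
        sigma_d = params$sigma_d %||% 1,
        sigma_r = params$sigma_r %||% 0.1,
        spatial_squared = params$spatial_squared %||% FALSE)
  } else {
    gl <- luminance(g)
    for (k in seq_len(dim(out)[3]))
      out[, , k] <- guided_filter(stack$values[, , k], gl,
                                  r = params$r %||% 1,
                                  epsilon = params$epsilon %||% 0.01)
  }
  probability_stack(clip01(out), stack$legend)
}
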