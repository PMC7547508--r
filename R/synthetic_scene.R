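# Fully synthetic hyperspectral scenes with known ground truth.
#
# The generator emulates a severely defoliated pure pine stand as seen by a
# co-flown hyperspectral imager and RGB camera:
#   - a K-class cover map with smooth, irregular crown-like boundaries, with
#     the damaged-pine class dominating the scene and bright classes (bare
#     land) minor, as in a heavily damaged stand;
#   - canopy-shading speckle: a patchy field that mixes pixels towards the
#     shadow signature identically in the cube and in the guidance (both
#     sensors image the same canopy);
#   - a smooth within-stand defoliation gradient that slides damaged-pine
#     pixels between the vegetation and fully-defoliated signatures, again
#     rendered consistently in both rasters;
#   - boundary mixing: band-wise Gaussian blur of the cube (mixed pixels at
#     crown edges), against a much sharper guidance image;
#   - spatially correlated sensor noise (hyperspectral frames are acquired at
#     coarse resolution and pan-sharpened, so per-pixel noise is correlated
#     across neighbouring pixels, not white).
# The speckle and defoliation-gradient features key on the standard class
# names ("shadow", "damaged_pine", "understory_vegetation") and are skipped
# for scenes that do not carry them.

#' Synthetic scene specification
#'
#' Defaults describe the study conditions the package is validated under:
#' a 200 x 200 scene with four cover classes (bare land, understory
#' vegetation, shadow, damaged pine), 40 bands across 450-950 nm, additive
#' noise sd 0.05 correlated over ~1.5 px, boundary-mixing blur of 1.5 px
#' against a much sharper (0.5 px) guidance image.
#'
#' @param H,W scene size in pixels.
#' @param K number of classes (>= 2).
#' @param B number of bands (>= 3).
#' @param class_names length-K class names.
#' @param wavelengths_nm band centres, ascending, length B.
#' @param noise_sd additive reflectance noise sd per band (partially
#'   correlated across bands through a shared per-pixel component, and
#'   spatially correlated over `noise_scale` pixels).
#' @param noise_scale spatial correlation length of the noise in pixels
#'   (0 = white noise).
#' @param sigma_mix band-wise Gaussian blur of the cube in pixels (mixed
#'   boundary pixels); 0 disables mixing.
#' @param guidance_blur Gaussian blur of the guidance image, pixels; smaller
#'   than `sigma_mix` (the guidance is the sharper image).
#' @param guidance_shift length-2 (dy, dx) misregistration of the guidance in
#'   pixels (may be fractional).
#' @param label_smoothness correlation length (pixels) of the random fields
#'   whose argmax forms the label map.
#' @param class_offsets length-K mean offsets of those fields, controlling
#'   class area shares. `NULL` = damaged-dominant composition for the
#'   standard four classes, equal shares otherwise.
#' @param speckle list(`amp`, `scale`, `threshold`): canopy-shading speckle
#'   mixing pixels towards the shadow signature; `amp = 0` disables.
#' @param damage_variation list(`scale`, `min`): smooth defoliation intensity
#'   in \[`min`, 1\] for damaged-pine pixels; `min = 1` disables.
#' @param class_spectra optional K x B matrix overriding [class_mean_spectra()].
#' @param seed integer seed; every generator output is deterministic in it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(H = 200L, W = 200L, K = 4L, B = 40L,
                       class_names = NULL,
                       wavelengths_nm = seq(450, 950, length.out = B),
                       noise_sd = 0.05, noise_scale = 1.5, sigma_mix = 1.5,
                       guidance_blur = 0.5, guidance_shift = c(0, 0),
                       label_smoothness = 12, class_offsets = NULL,
                       speckle = list(amp = 1, scale = 2.5, threshold = 0.5),
                       damage_variation = list(scale = 5, min = 0.35),
                       class_spectra = NULL, seed = 0L) {
  if (K < 2L) abort("K must be >= 2", "bad_value")
  if (B < 3L) abort("B must be >= 3", "bad_value")
  if (noise_sd < 0 || sigma_mix < 0 || guidance_blur < 0 || noise_scale < 0)
    abort("noise and blur scales must be >= 0", "bad_value")
  standard4 <- c("bare_land", "understory_vegetation", "shadow", "damaged_pine")
  if (is.null(class_names))
    class_names <- if (K == 4L) standard4 else paste0("class_", seq_len(K))
  if (length(class_names) != K) abort("need one class name per class", "bad_value")
  if (is.null(class_offsets))
    class_offsets <- if (identical(class_names, standard4))
      c(-0.45, -0.3, 0.2, 0.7) else rep(0, K)
  if (length(class_offsets) != K) abort("need one class offset per class", "bad_value")
  structure(list(H = as.integer(H), W = as.integer(W), K = as.integer(K),
                 B = as.integer(B), class_names = class_names,
                 wavelengths_nm = wavelengths_nm, noise_sd = noise_sd,
                 noise_scale = noise_scale, sigma_mix = sigma_mix,
                 guidance_blur = guidance_blur, guidance_shift = guidance_shift,
                 label_smoothness = label_smoothness,
                 class_offsets = class_offsets, speckle = speckle,
                 damage_variation = damage_variation,
                 class_spectra = class_spectra, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Per-class mean spectra of a scene
#'
#' For the standard four classes the curves mimic field reflectance: bright
#' soil rising through the visible; green vegetation with a 550 nm bump and a
#' strong red edge into the NIR plateau; dark flat shadow; and defoliated
#' (brown) pine with elevated red and a weak NIR response. Other class counts
#' get distinct smooth procedural curves.
#'
#' @param spec a [scene_spec()].
#' @return K x B matrix of mean reflectances in \[0, 1\].
#' @export
class_mean_spectra <- function(spec) {
  if (!is.null(spec$class_spectra)) {
    s <- as.matrix(spec$class_spectra)
    if (any(dim(s) != c(spec$K, spec$B)))
      abort("class_spectra must be K x B", "bad_dims")
    rownames(s) <- spec$class_names
    return(s)
  }
  wl <- spec$wavelengths_nm
  u <- (wl - 450) / 500
  std <- list(
    bare_land = 0.14 + 0.24 * u + 0.03 * sin(3 * u),
    understory_vegetation = 0.04 + 0.07 * exp(-((wl - 550) / 30)^2) +
      0.40 / (1 + exp(-(wl - 715) / 12)),
    shadow = 0.02 + 0.04 * u,
    damaged_pine = 0.08 + 0.14 * u + 0.10 / (1 + exp(-(wl - 720) / 15))
  )
  out <- matrix(0, spec$K, spec$B)
  for (k in seq_len(spec$K)) {
    nm <- spec$class_names[k]
    out[k, ] <- if (!is.null(std[[nm]])) std[[nm]]
      else clip01(0.3 + 0.25 * sin(2 * pi * u * (0.5 + 0.25 * k) + 2.4 * k))
  }
  rownames(out) <- spec$class_names
  clip01(out)
}

#' Per-class guidance colours
#'
#' Bright tan soil, dark green understory, near-black shadow and bright
#' red-brown defoliated crowns: the full dynamic range a camera sees over a
#' damaged stand. Other class counts get evenly spaced hues.
#'
#' @param spec a [scene_spec()].
#' @return K x 3 matrix of RGB colours in \[0, 1\].
#' @export
class_colors <- function(spec) {
  std <- rbind(bare_land = c(0.55, 0.50, 0.40),
               understory_vegetation = c(0.13, 0.30, 0.13),
               shadow = c(0.02, 0.02, 0.04),
               damaged_pine = c(0.95, 0.85, 0.70))
  out <- matrix(0, spec$K, 3L)
  for (k in seq_len(spec$K)) {
    nm <- spec$class_names[k]
    out[k, ] <- if (nm %in% rownames(std)) std[nm, ]
      else t(grDevices::col2rgb(grDevices::hsv((k - 1) / spec$K, 0.6, 0.7)) / 255)[1, ]
  }
  rownames(out) <- spec$class_names
  out
}

unit_smooth_field <- function(H, W, sigma) {
  f <- gaussian_blur(matrix(rnorm(H * W), H, W), sigma)
  f / stats::sd(f)
}

#' Generate the ground-truth label map of a scene
#'
#' K independent Gaussian random fields are smoothed to the requested
#' correlation length, shifted by the class area offsets, and the per-pixel
#' argmax yields contiguous regions with irregular boundaries. For K = 2 a
#' single smoothed field is thresholded at its median, which balances the two
#' class areas exactly. Deterministic in `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return a [label_map()].
#' @export
generate_label_map <- function(spec) {
  set.seed(spec$seed)
  if (spec$K == 2L) {
    f <- unit_smooth_field(spec$H, spec$W, spec$label_smoothness)
    lab <- matrix(1L + (f > stats::median(f)), spec$H, spec$W)
  } else {
    fields <- matrix(0, spec$H * spec$W, spec$K)
    for (k in seq_len(spec$K))
      fields[, k] <- unit_smooth_field(spec$H, spec$W, spec$label_smoothness) +
        spec$class_offsets[k]
    lab <- matrix(max.col(fields, ties.method = "first"), spec$H, spec$W)
  }
  label_map(lab, spec$class_names)
}

# Shared scene state seen by both sensors: the shading-speckle field and the
# defoliation-intensity field. Deterministic in spec$seed, independent of the
# RNG state of the caller.
scene_fields <- function(spec) {
  shade <- NULL
  if (spec$speckle$amp > 0 && "shadow" %in% spec$class_names) {
    set.seed(spec$seed + 10L)
    z <- unit_smooth_field(spec$H, spec$W, spec$speckle$scale)
    shade <- spec$speckle$amp * stats::plogis((z - spec$speckle$threshold) * 4)
  }
  dmg <- NULL
  if (spec$damage_variation$min < 1 &&
      all(c("damaged_pine", "understory_vegetation") %in% spec$class_names)) {
    set.seed(spec$seed + 20L)
    z <- unit_smooth_field(spec$H, spec$W, spec$damage_variation$scale)
    mid <- (1 + spec$damage_variation$min) / 2
    dmg <- mid + (1 - mid) * tanh(z)
  }
  list(shade = shade, damage = dmg)
}

# Render one channel (a length-K palette) of the scene to a matrix, applying
# the defoliation gradient and the shading speckle.
render_channel <- function(lab, palette, fields, class_names) {
  m <- matrix(palette[as.vector(lab)], nrow(lab), ncol(lab))
  if (!is.null(fields$damage)) {
    d <- which(class_names == "damaged_pine")
    v <- which(class_names == "understory_vegetation")
    sel <- lab == d
    m[sel] <- (fields$damage * palette[d] + (1 - fields$damage) * palette[v])[sel]
  }
  if (!is.null(fields$shade)) {
    s <- which(class_names == "shadow")
    m <- (1 - fields$shade) * m + fields$shade * palette[s]
  }
  m
}

#' Render the hyperspectral cube of a scene
#'
#' Each pixel starts from its class mean spectrum, modulated by the scene's
#' defoliation gradient and shading speckle; band-wise Gaussian blur of width
#' `sigma_mix` then mixes spectra across region boundaries; finally additive
#' noise (a shared per-pixel component plus band noise, total sd `noise_sd`,
#' spatially correlated over `noise_scale` px) is applied and values are
#' clipped to \[0, 1\]. Deterministic in `spec$seed`.
#'
#' @param labels the scene's [label_map()].
#' @param spec the matching [scene_spec()].
#' @return a [hyperspectral_cube()].
#' @export
render_cube <- function(labels, spec) {
  if (any(dim(labels$values) != c(spec$H, spec$W)))
    abort("labels do not match the scene spec", "bad_dims")
  if (anyNA(labels$values) || max(labels$values) > spec$K)
    abort("unknown label value", "bad_value")
  spectra <- class_mean_spectra(spec)
  fields <- scene_fields(spec)
  cube <- array(0, c(spec$H, spec$W, spec$B))
  for (b in seq_len(spec$B))
    cube[, , b] <- render_channel(labels$values, spectra[, b], fields, spec$class_names)
  if (spec$sigma_mix > 0) cube <- gaussian_blur(cube, spec$sigma_mix)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 1L)
    draw <- function() {
      n <- matrix(rnorm(spec$H * spec$W), spec$H, spec$W)
      if (spec$noise_scale > 0) {
        n <- gaussian_blur(n, spec$noise_scale)
        n <- n / stats::sd(n)
      }
      n
    }
    common <- draw()
    for (b in seq_len(spec$B))
      cube[, , b] <- cube[, , b] + spec$noise_sd * (0.5 * common + sqrt(0.75) * draw())
  }
  hyperspectral_cube(clip01(cube), wavelengths_nm = spec$wavelengths_nm)
}

#' Render the guidance image of a scene
#'
#' Per-class colours modulated by the same defoliation gradient and shading
#' speckle as the cube (both sensors image the same canopy), blurred by
#' `guidance_blur` (strictly sharper than the cube's `sigma_mix` under the
#' defaults) and optionally shifted by a sub-pixel misregistration offset.
#'
#' @param labels the scene's [label_map()].
#' @param spec the matching [scene_spec()].
#' @return a [guidance_image()] with provenance `"synthetic"`.
#' @export
render_guidance <- function(labels, spec) {
  if (any(dim(labels$values) != c(spec$H, spec$W)))
    abort("labels do not match the scene spec", "bad_dims")
  cols <- class_colors(spec)
  fields <- scene_fields(spec)
  g <- array(0, c(spec$H, spec$W, 3L))
  for (c in 1:3)
    g[, , c] <- render_channel(labels$values, cols[, c], fields, spec$class_names)
  if (spec$guidance_blur > 0) g <- gaussian_blur(g, spec$guidance_blur)
  if (any(spec$guidance_shift != 0))
    g <- shift_bilinear(g, spec$guidance_shift[1], spec$guidance_shift[2])
  guidance_image(clip01(g), provenance = "synthetic")
}

#' Draw a labelled pixel sample set from a scene
#'
#' Samples `n_per_class` distinct pixels per class (without replacement) and
#' splits them into training and verification roles, stratified per class.
#'
#' @param labels the scene's [label_map()].
#' @param n_per_class samples per class.
#' @param train_fraction fraction assigned to training (3:1 split by default).
#' @param seed RNG seed.
#' @return a [sample_set()].
#' @export
sample_scene <- function(labels, n_per_class = 1250L, train_fraction = 0.75,
                         seed = 0L) {
  set.seed(seed)
  K <- length(labels$legend)
  recs <- list()
  for (k in seq_len(K)) {
    idx <- which(labels$values == k)
    if (length(idx) < n_per_class)
      abort(sprintf("class %s has only %d pixels (< %d requested)",
                    labels$legend[k], length(idx), n_per_class), "bad_samples")
    chosen <- sample(idx, n_per_class)
    n_tr <- round(n_per_class * train_fraction)
    H <- nrow(labels$values)
    recs[[k]] <- data.frame(
      row = ((chosen - 1L) %% H) + 1L,
      col = ((chosen - 1L) %/% H) + 1L,
      class_id = k,
      role = rep(c("training", "verification"), c(n_tr, n_per_class - n_tr)))
  }
  sample_set(do.call(rbind, recs), legend = labels$legend,
             raster_shape = dim(labels$values))
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper running [generate_label_map()], [render_cube()],
#' [render_guidance()] and [sample_scene()].
#'
#' @param spec a [scene_spec()].
#' @param n_per_class,train_fraction passed to [sample_scene()].
#' @return list with `labels`, `cube`, `guidance`, `samples`, `spec`.
#' @export
synth_scene <- function(spec = scene_spec(), n_per_class = 1250L,
                        train_fraction = 0.75) {
  labels <- generate_label_map(spec)
  list(labels = labels,
       cube = render_cube(labels, spec),
       guidance = render_guidance(labels, spec),
       samples = sample_scene(labels, n_per_class, train_fraction,
                              seed = spec$seed + 2L),
       spec = spec)
}

#' Pixels near an inter-class boundary
#'
#' Logical mask of pixels whose Chebyshev distance to a differently-labelled
#' pixel is at most `radius`. Used to measure boundary-specific error rates.
#'
#' @param labels a [label_map()].
#' @param radius neighbourhood radius in pixels.
#' @return logical H x W matrix.
#' @export
boundary_mask <- function(labels, radius = 2L) {
  v <- labels$values
  h <- nrow(v); w <- ncol(v)
  p <- pad_reflect(v, radius)
  out <- matrix(FALSE, h, w)
  ri <- (1L + radius):(h + radius); ci <- (1L + radius):(w + radius)
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dy == 0L && dx == 0L) next
    out <- out | (p[ri + dy, ci + dx] != v)
  }
  out
}
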