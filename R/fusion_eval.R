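# Maximum-probability fusion, accuracy assessment (OA / Kappa / per-class
# producer accuracy), MSSIM edge-preservation scoring, crown-mask extraction
# and the needle-count defoliation rate.

resolve_class <- function(class, legend) {
  if (is.character(class)) {
    id <- match(class, legend)
    if (is.na(id)) abort(paste("class not in legend:", class), "bad_legend")
    return(id)
  }
  id <- as.integer(class)
  if (is.na(id) || id < 1L || id > length(legend))
    abort("class id outside the legend", "bad_legend")
  id
}

#' Fuse a probability stack into a label map
#'
#' Per-pixel argmax over the K class layers; exact ties are broken by the
#' lowest class index, so the result is deterministic and invariant to
#' per-pixel positive rescaling of the stack.
#'
#' @param stack a [probability_stack()].
#' @return a [label_map()] over the stack's legend.
#' @export
fuse_max_probability <- function(stack) {
  d <- dim(stack$values)
  if (d[3] < 2L) abort("stack must have K >= 2 layers", "bad_dims")
  if (anyNA(stack$values)) abort("stack contains NA/NaN", "bad_value")
  m <- matrix(stack$values, d[1] * d[2], d[3])
  lab <- matrix(max.col(m, ties.method = "first"), d[1], d[2])
  label_map(lab, stack$legend)
}

# ---- confusion-matrix metrics ------------------------------------------------

confusion_matrix <- function(truth_id, pred_id, K) {
  cm <- table(factor(truth_id, levels = seq_len(K)),
              factor(pred_id, levels = seq_len(K)))
  matrix(as.integer(cm), K, K)   # rows = truth, cols = predicted
}

overall_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

kappa_coefficient <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

producer_accuracy <- function(cm) {
  rs <- rowSums(cm)
  ifelse(rs > 0, diag(cm) / rs, NA_real_)
}

#' Accuracy assessment of a classification
#'
#' Builds the confusion matrix of a predicted label map against reference
#' labels and reports overall accuracy (OA), Cohen's kappa, per-class
#' producer accuracy, and CADP — the producer accuracy (recall) of the
#' damaged-pine class, i.e. the extraction accuracy of damaged crowns.
#'
#' @param pred a [label_map()].
#' @param truth either a [sample_set()] (only records with role
#'   `"verification"` are scored) or a [label_map()] (all non-nodata pixels).
#' @param damaged_class name or id of the damaged class (default: last legend
#'   entry).
#' @return an `evaluation_report`: list with `confusion` (rows = truth),
#'   `OA`, `Kappa`, `producer_accuracy`, `CADP`, `n`.
#' @export
evaluate_classification <- function(pred, truth, damaged_class = NULL) {
  legend <- pred$legend
  K <- length(legend)
  if (inherits(truth, "sample_set")) {
    ve <- truth[truth$role == "verification", , drop = FALSE]
    truth_id <- ve$class_id
    pred_id <- pred$values[cbind(ve$row, ve$col)]
  } else if (inherits(truth, "label_map")) {
    keep <- !is.na(truth$values) & !is.na(pred$values)
    truth_id <- truth$values[keep]
    pred_id <- pred$values[keep]
  } else abort("truth must be a sample_set or a label_map", "bad_value")
  missing <- setdiff(seq_len(K), unique(truth_id))
  if (length(missing))
    abort(paste("class(es) absent from the reference labels:",
                paste(legend[missing], collapse = ", ")), "bad_samples")
  dmg <- resolve_class(damaged_class %||% K, legend)
  cm <- confusion_matrix(truth_id, pred_id, K)
  pa <- producer_accuracy(cm)
  structure(list(confusion = cm, legend = legend,
                 OA = overall_accuracy(cm), Kappa = kappa_coefficient(cm),
                 producer_accuracy = setNames(pa, legend),
                 CADP = pa[dmg], damaged_class = legend[dmg], n = sum(cm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d\n", x$n))
  cm <- x$confusion
  dimnames(cm) <- list(truth = x$legend, predicted = x$legend)
  print(cm)
  cat(sprintf("OA = %.4f  Kappa = %.4f  CADP(%s) = %.4f\n",
              x$OA, x$Kappa, x$damaged_class, x$CADP))
  invisible(x)
}

# ---- MSSIM -------------------------------------------------------------------

#' Mean structural similarity index
#'
#' MSSIM between a guidance image and a filtered probability map: the mean
#' over all pixels of the local SSIM
#' \deqn{\frac{(2\mu_I\mu_Q + c_1)(2\sigma_{IQ} + c_2)}
#'            {(\mu_I^2+\mu_Q^2+c_1)(\sigma_I^2+\sigma_Q^2+c_2)}}
#' with `c1 = (K1 L)^2`, `c2 = (K2 L)^2`, `K1 = 0.01`, `K2 = 0.03`. Local
#' statistics use a Gaussian-weighted window (default 11 x 11, sigma 1.5 —
#' the standard SSIM protocol) with mirrored borders. A 3-channel image is
#' reduced to luminance first, so the comparison is always single-channel.
#'
#' @param i_img guidance image: matrix, H x W x 3 array or [guidance_image()].
#' @param q_img filtered map: same spatial shape.
#' @param window odd window side length.
#' @param L dynamic range of the pixel values (1 for \[0, 1\] images).
#' @return scalar in (-1, 1]; 1 iff the images are identical.
#' @export
mssim <- function(i_img, q_img, window = 11L, L = 1) {
  I <- luminance(guidance_values(i_img))
  Q <- luminance(guidance_values(q_img))
  if (any(dim(I) != dim(Q))) abort("images must have the same shape", "bad_dims")
  if (L <= 0) abort("dynamic range L must be > 0", "bad_value")
  if (window %% 2L != 1L || window < 3L) abort("window must be an odd integer >= 3", "bad_value")
  radius <- (window - 1L) %/% 2L
  gb <- function(x) gaussian_blur(x, sigma = 1.5, radius = radius)
  mu_i <- gb(I); mu_q <- gb(Q)
  var_i <- gb(I * I) - mu_i^2
  var_q <- gb(Q * Q) - mu_q^2
  cov_iq <- gb(I * Q) - mu_i * mu_q
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  ssim <- ((2 * mu_i * mu_q + c1) * (2 * cov_iq + c2)) /
          ((mu_i^2 + mu_q^2 + c1) * (var_i + var_q + c2))
  mean(ssim)
}

# ---- crown extraction --------------------------------------------------------

#' Extract the damaged-crown mask from a label map
#'
#' Binary mask of pixels assigned to the damaged class, with 8-connected
#' component labelling (diagonally touching crowns merge into one component,
#' matching how adjoining crowns appear in imagery).
#'
#' @param map a [label_map()].
#' @param damaged_class name or id of the damaged class.
#' @return list with `mask` (logical H x W), `components` (integer H x W,
#'   0 = background), `n_components`, and `areas_px` (pixels per component).
#' @export
extract_crown_mask <- function(map, damaged_class) {
  dmg <- resolve_class(damaged_class, map$legend)
  mask <- !is.na(map$values) & map$values == dmg
  comp <- label_components8(mask)
  n <- max(comp)
  areas <- if (n > 0L) tabulate(comp[comp > 0L], nbins = n) else integer(0)
  list(mask = mask, components = comp, n_components = n, areas_px = areas)
}

# ---- defoliation rate --------------------------------------------------------

#' Needle-count defoliation rate of a sampled tree
#'
#' Standard branches are scored in three crown layers (upper, middle, lower);
#' in each layer the needles are counted into loss levels 0, 25, 50, 75 and
#' 100 percent. The layer rate is the count-weighted mean loss level and the
#' tree-level rate is the arithmetic mean of the three layer rates.
#'
#' @param counts 3 x 5 numeric matrix or data.frame: rows = layers (upper,
#'   middle, lower), columns = needle counts at loss levels 0/25/50/75/100%.
#' @return the tree-level defoliation rate in percent, with the per-layer
#'   rates attached as attribute `layer_rates`.
#' @export
defoliation_rate <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 3L || ncol(counts) != 5L)
    abort("counts must be 3 layers x 5 loss levels", "bad_dims")
  if (any(counts < 0)) abort("needle counts must be >= 0", "bad_value")
  totals <- rowSums(counts)
  if (any(totals <= 0)) abort("every layer needs a positive needle count", "bad_value")
  levels_pct <- c(0, 25, 50, 75, 100)
  p_i <- as.vector(counts %*% levels_pct) / totals
  structure(sum(p_i) / 3, layer_rates = p_i)
}
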