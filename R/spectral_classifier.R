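# Pixel-wise SVM classification with the Gaussian radial-basis kernel
# K(x_i, x) = exp(-||x - x_i||^2 / gamma^2), gamma > 0.
#
# Note on parameterization: libsvm (and hence e1071) writes the RBF kernel as
# exp(-g * ||x - x_i||^2), so the kernel width `gamma` used throughout this
# package maps to g = 1 / gamma^2. gamma = 0.5 therefore means g = 4.

cube_feature_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, d[1] * d[2], d[3])
}

sample_features <- function(cube, samples) {
  d <- dim(cube$values)
  idx <- (samples$col - 1L) * d[1] + samples$row
  cube_feature_matrix(cube)[idx, , drop = FALSE]
}

#' Train a pixel-wise SVM with the Gaussian radial-basis kernel
#'
#' Fits a multiclass SVM (one-vs-one, as realized by libsvm) on the training
#' records of `samples`, with Platt-style per-pair sigmoid probability
#' calibration coupled into multiclass probabilities. Features are the band
#' reflectances of each sampled pixel on the \[0, 1\] scale that the readers
#' normalize to; the kernel width is interpreted on that scale, where
#' within-class squared distances are O(0.1) and `gamma` of order 0.5 is a
#' sensible width. (Per-band standardization would inflate squared distances
#' to the order of the band count and collapse the kernel matrix towards the
#' identity at such widths.)
#'
#' @param cube a [hyperspectral_cube()].
#' @param samples a [sample_set()]; only records with role `"training"` are used.
#' @param C penalty coefficient, > 0.
#' @param gamma kernel width in the form `exp(-||x - x_i||^2 / gamma^2)`, > 0.
#' @param seed RNG seed for the internal calibration cross-validation folds.
#' @return an object of class `svm_grbf` holding the fitted libsvm model, the
#'   per-band centring/scaling, the class legend and the training parameters.
#' @export
train_svm_grbf <- function(cube, samples, C = 20, gamma = 0.5, seed = 0L) {
  if (!is.numeric(C) || C <= 0) abort("C must be a positive scalar", "bad_value")
  if (!is.numeric(gamma) || gamma <= 0) abort("gamma must be a positive scalar", "bad_value")
  legend <- attr(samples, "legend")
  tr <- samples[samples$role == "training", , drop = FALSE]
  if (length(unique(tr$class_id)) < 2L)
    abort("training samples must contain at least 2 classes", "bad_samples")
  x <- sample_features(cube, tr)
  if (any(!is.finite(x))) abort("training features must be finite", "bad_value")
  y <- factor(legend[tr$class_id], levels = legend)
  set.seed(seed)
  fit <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = 1 / gamma^2,
                    probability = TRUE, scale = FALSE)
  structure(list(fit = fit, legend = legend,
                 n_bands = ncol(x), C = C, gamma = gamma, seed = seed),
            class = "svm_grbf")
}

#' @export
print.svm_grbf <- function(x, ...) {
  cat(sprintf("<svm_grbf> C = %g, gamma = %g, %d bands, %d classes, %d support vectors\n",
              x$C, x$gamma, x$n_bands, length(x$legend), nrow(x$fit$SV)))
  invisible(x)
}

predict_probabilities <- function(model, features) {
  pr <- attr(stats::predict(model$fit, features, probability = TRUE), "probabilities")
  pr[, model$legend, drop = FALSE]  # columns in legend order
}

#' Per-class probability maps for every pixel of a cube
#'
#' Applies a trained model to all pixels and returns the initial probability
#' stack: an H x W x K array whose per-pixel values are the coupled class
#' probabilities (summing to 1). The stack's per-pixel argmax is, by
#' definition, the pipeline's hard label (see [fuse_max_probability()]); near
#' ties it may differ from libsvm's internal voting label.
#'
#' @param model an `svm_grbf` model.
#' @param cube a [hyperspectral_cube()] with the same band count the model was
#'   trained on.
#' @return an object of class `probability_stack`: list with `values`
#'   (H x W x K) and `legend`.
#' @export
predict_probability_stack <- function(model, cube) {
  d <- dim(cube$values)
  if (d[3] != model$n_bands)
    abort(sprintf("cube has %d bands but the model expects %d", d[3], model$n_bands),
          "bad_dims")
  pr <- predict_probabilities(model, cube_feature_matrix(cube))
  probability_stack(array(pr, c(d[1], d[2], ncol(pr))), model$legend)
}

#' Probability stack container
#'
#' @param values numeric H x W x K array of per-class probabilities in \[0, 1\].
#' @param legend class names, length K.
#' @export
probability_stack <- function(values, legend) {
  if (length(dim(values)) != 3L) abort("stack values must be H x W x K", "bad_dims")
  if (dim(values)[3] != length(legend))
    abort("stack depth must equal the number of classes", "bad_dims")
  structure(list(values = values, legend = as.character(legend)),
            class = "probability_stack")
}

#' @export
print.probability_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<probability_stack> %d x %d, classes: %s\n", d[1], d[2],
              paste(x$legend, collapse = ", ")))
  invisible(x)
}

#' Grid search over (C, gamma)
#'
#' Trains one model per grid point on the training split and scores it on the
#' verification split with OA, Kappa and CADP (producer accuracy of the
#' damaged class). The best combination maximizes `criterion`; exact ties are
#' broken deterministically by smaller C, then larger gamma. Per-fit wall time
#' is reported for information only.
#'
#' @param cube a [hyperspectral_cube()].
#' @param samples a [sample_set()] with disjoint training/verification roles.
#' @param C_grid,gamma_grid non-empty numeric vectors. Defaults follow the
#'   region commonly explored for this problem.
#' @param criterion which column to maximize.
#' @param damaged_class name or id of the damaged class (default: last legend
#'   entry).
#' @param seed seed passed to every [train_svm_grbf()] call.
#' @return a `grid_search_report`: data.frame with columns C, gamma, OA,
#'   Kappa, CADP, fit_time_s, and attribute `best` (the selected row).
#' @export
grid_search <- function(cube, samples,
                        C_grid = c(5, 10, 15, 20, 40, 60, 80, 100),
                        gamma_grid = c(0.5, 1),
                        criterion = c("OA", "CADP", "Kappa"),
                        damaged_class = NULL, seed = 0L) {
  criterion <- match.arg(criterion)
  if (length(C_grid) < 1L || length(gamma_grid) < 1L)
    abort("parameter grids must be non-empty", "bad_value")
  legend <- attr(samples, "legend")
  tr <- samples[samples$role == "training", ]
  ve <- samples[samples$role == "verification", ]
  if (nrow(merge(tr[c("row", "col")], ve[c("row", "col")])) > 0L)
    abort("training and verification samples overlap", "bad_samples")
  if (nrow(ve) == 0L) abort("no verification samples", "bad_samples")
  dmg <- resolve_class(damaged_class %||% length(legend), legend)
  vx <- sample_features(cube, ve)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    t0 <- proc.time()[["elapsed"]]
    model <- train_svm_grbf(cube, samples, C = grid$C[i], gamma = grid$gamma[i], seed = seed)
    pr <- predict_probabilities(model, vx)
    pred_id <- max.col(pr, ties.method = "first")
    cm <- confusion_matrix(ve$class_id, pred_id, length(legend))
    data.frame(C = grid$C[i], gamma = grid$gamma[i],
               OA = overall_accuracy(cm), Kappa = kappa_coefficient(cm),
               CADP = producer_accuracy(cm)[dmg],
               fit_time_s = proc.time()[["elapsed"]] - t0)
  })
  report <- do.call(rbind, rows)
  ord <- order(-report[[criterion]], report$C, -report$gamma)
  best <- report[ord[1L], ]
  structure(report, best = best, criterion = criterion,
            class = c("grid_search_report", "data.frame"))
}

#' @export
print.grid_search_report <- function(x, ...) {
  cat(sprintf("<grid_search_report> %d combinations, criterion: %s\n",
              nrow(x), attr(x, "criterion")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  b <- attr(x, "best")
  cat(sprintf("selected: C = %g, gamma = %g (%s = %.4f)\n",
              b$C, b$gamma, attr(x, "criterion"), b[[attr(x, "criterion")]]))
  invisible(x)
}

#' @rdname grid_search
#' @param report a `grid_search_report`.
#' @param path CSV output path.
#' @export
write_grid_search_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
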