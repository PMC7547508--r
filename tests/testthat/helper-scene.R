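# Shared fixtures, generated in code. The small scene keeps per-file test
# cost low; it is cached per session since several files only read from it.

.scene_cache <- new.env(parent = emptyenv())

small_scene <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.scene_cache[[key]])) {
    spec <- scene_spec(H = 96L, W = 96L, B = 20L, label_smoothness = 8,
                       seed = seed)
    .scene_cache[[key]] <- synth_scene(spec, n_per_class = 220L)
  }
  .scene_cache[[key]]
}

small_model <- function(seed = 1L) {
  key <- paste0("m", seed)
  if (is.null(.scene_cache[[key]])) {
    scn <- small_scene(seed)
    .scene_cache[[key]] <- train_svm_grbf(scn$cube, scn$samples, seed = seed)
  }
  .scene_cache[[key]]
}

small_stack <- function(seed = 1L) {
  key <- paste0("p", seed)
  if (is.null(.scene_cache[[key]])) {
    scn <- small_scene(seed)
    .scene_cache[[key]] <- predict_probability_stack(small_model(seed), scn$cube)
  }
  .scene_cache[[key]]
}

# a cube whose "pixels" are arbitrary feature vectors: n x 1 x B
feature_cube <- function(x) {
  hyperspectral_cube(array(x, c(nrow(x), 1L, ncol(x))))
}

feature_samples <- function(y, legend = NULL, role = "training") {
  legend <- legend %||% paste0("class_", sort(unique(y)))
  sample_set(data.frame(row = seq_along(y), col = 1L, class_id = y, role = role),
             legend = legend)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
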