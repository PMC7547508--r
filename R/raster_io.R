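# Raster and sample-table IO.
#
# Conventions used throughout the package: arrays are indexed (row, col[, band]),
# 1-based, row 1 at the top; reflectance and guidance intensities live in [0, 1].
# Cubes and label maps round-trip through ENVI (text .hdr + flat binary) or
# plain multi-directory TIFF; guidance images through PNG (8-bit) or TIFF
# (float32); sample tables through CSV.

# ---- containers --------------------------------------------------------------

#' Hyperspectral reflectance cube
#'
#' Container for an H x W x B reflectance raster. `NaN` values are converted to
#' `NA` (masked). Integer digital numbers should be normalized to \[0, 1\]
#' before construction (the readers do this automatically using the data type's
#' declared maximum), because the range parameters of the edge-preserving
#' filters (`sigma_r`, `epsilon`) are only meaningful on normalized intensities.
#'
#' @param values numeric H x W x B array (a matrix is treated as B = 1).
#' @param wavelengths_nm optional strictly increasing vector of band-centre
#'   wavelengths in nanometres, length B.
#' @param pixel_size_m optional ground sampling distance in metres.
#' @return an object of class `hyperspectral_cube` with elements `values`,
#'   `wavelengths_nm`, `pixel_size_m`.
#' @export
hyperspectral_cube <- function(values, wavelengths_nm = NULL, pixel_size_m = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L)
    abort("cube values must be an H x W x B array", "bad_dims")
  if (any(dim(values) < 1L)) abort("cube dimensions must be >= 1", "bad_dims")
  values[is.nan(values)] <- NA_real_
  if (!is.null(wavelengths_nm)) {
    if (length(wavelengths_nm) != dim(values)[3])
      abort("wavelengths_nm must have one entry per band", "bad_dims")
    if (any(diff(wavelengths_nm) <= 0))
      abort("wavelengths_nm must be strictly increasing", "bad_value")
  }
  structure(list(values = values, wavelengths_nm = wavelengths_nm,
                 pixel_size_m = pixel_size_m),
            class = "hyperspectral_cube")
}

#' @export
dim.hyperspectral_cube <- function(x) dim(x$values)

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyperspectral_cube> %d x %d pixels, %d bands", d[1], d[2], d[3]))
  if (!is.null(x$wavelengths_nm))
    cat(sprintf(", %.0f-%.0f nm", min(x$wavelengths_nm), max(x$wavelengths_nm)))
  cat("\n")
  invisible(x)
}

#' Guidance image
#'
#' A single- or 3-channel image in \[0, 1\] supplying edge structure to the
#' edge-preserving filters (a resampled RGB frame, a PCA false-colour
#' composite, or a synthetic rendering).
#'
#' @param values numeric H x W matrix or H x W x 3 array with values in \[0, 1\].
#' @param provenance one of `"rgb_resampled"`, `"pca_false_color"`, `"synthetic"`.
#' @return an object of class `guidance_image`.
#' @export
guidance_image <- function(values,
                           provenance = c("rgb_resampled", "pca_false_color", "synthetic")) {
  provenance <- match.arg(provenance)
  if (!(is.matrix(values) || (length(dim(values)) == 3L && dim(values)[3] == 3L)))
    abort("guidance values must be H x W or H x W x 3", "bad_dims")
  if (anyNA(values)) abort("guidance image must not contain NA", "bad_value")
  if (min(values) < 0 || max(values) > 1)
    abort("guidance values must lie in [0, 1]", "bad_value")
  structure(list(values = values, provenance = provenance), class = "guidance_image")
}

#' @export
print.guidance_image <- function(x, ...) {
  d <- dim(x$values)
  ch <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<guidance_image> %d x %d, %d channel(s), provenance: %s\n",
              d[1], d[2], ch, x$provenance))
  invisible(x)
}

#' Categorical label map
#'
#' An H x W raster of class labels. Internally classes are coded 1..K matching
#' the order of `legend`; `NA` marks nodata.
#'
#' @param values integer H x W matrix with entries in 1..K or `NA`.
#' @param legend character vector of class names, length K >= 2.
#' @return an object of class `label_map`.
#' @export
label_map <- function(values, legend) {
  if (!is.matrix(values)) abort("label values must be a matrix", "bad_dims")
  if (length(legend) < 2L) abort("legend must name at least 2 classes", "bad_legend")
  if (anyDuplicated(legend)) abort("legend entries must be unique", "bad_legend")
  storage.mode(values) <- "integer"
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 1L || max(v) > length(legend)))
    abort("label values must lie in 1..length(legend)", "bad_value")
  structure(list(values = values, legend = as.character(legend)), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, classes: %s\n", nrow(x$values), ncol(x$values),
              paste(x$legend, collapse = ", ")))
  invisible(x)
}

#' Labelled pixel sample set
#'
#' Point samples used to train and verify the classifier: one record per pixel
#' with 1-based (row, col) coordinates, a class id into `legend`, and a role
#' flag (`"training"` or `"verification"`).
#'
#' @param records data.frame with columns `row`, `col`, `class_id`, `role`.
#' @param legend character vector of class names.
#' @param raster_shape optional `c(H, W)` used for bounds checking.
#' @return an object of class `sample_set` (a data.frame with a `legend`
#'   attribute).
#' @export
sample_set <- function(records, legend, raster_shape = NULL) {
  need <- c("row", "col", "class_id", "role")
  if (!all(need %in% names(records)))
    abort(paste("sample records need columns:", paste(need, collapse = ", ")), "bad_samples")
  records <- records[need]
  records$row <- as.integer(records$row)
  records$col <- as.integer(records$col)
  records$class_id <- as.integer(records$class_id)
  records$role <- as.character(records$role)
  if (!all(records$role %in% c("training", "verification")))
    abort("role must be 'training' or 'verification'", "bad_samples")
  if (any(records$class_id < 1L) || any(records$class_id > length(legend)))
    abort("class_id out of range of the legend", "bad_samples")
  if (!is.null(raster_shape)) {
    if (any(records$row < 1L | records$row > raster_shape[1] |
            records$col < 1L | records$col > raster_shape[2]))
      abort("sample coordinates outside the raster bounds", "bad_samples")
  }
  if (anyDuplicated(records[c("row", "col")]))
    abort("duplicate (row, col) sample coordinates", "bad_samples")
  structure(records, legend = as.character(legend),
            class = c("sample_set", "data.frame"))
}

#' Assign training/verification roles by stratified splitting
#'
#' Splits the records of each class into training and verification roles
#' (default 3:1), reproducibly for a given seed.
#'
#' @param samples a [sample_set()] (roles are overwritten).
#' @param train_fraction fraction of each class assigned to training.
#' @param seed RNG seed.
#' @return the sample set with new roles.
#' @export
split_samples <- function(samples, train_fraction = 0.75, seed = 0L) {
  set.seed(seed)
  samples$role <- "verification"
  for (k in unique(samples$class_id)) {
    idx <- which(samples$class_id == k)
    n_tr <- round(length(idx) * train_fraction)
    samples$role[sample(idx, n_tr)] <- "training"
  }
  samples
}

# ---- ENVI header + binary ----------------------------------------------------

# minimal ENVI type table: code -> (R read type, bytes, signed, max for DN scaling)
.envi_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE, max = 255),
  `2`  = list(what = "integer", size = 2L, signed = TRUE,  max = 32767),
  `3`  = list(what = "integer", size = 4L, signed = TRUE,  max = 2147483647),
  `4`  = list(what = "double",  size = 4L, signed = TRUE,  max = NA),
  `5`  = list(what = "double",  size = 8L, signed = TRUE,  max = NA),
  `12` = list(what = "integer", size = 2L, signed = FALSE, max = 65535)
)

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  out <- list(); key <- NULL; buf <- NULL; open <- FALSE
  for (ln in lines) {
    if (!open) {
      m <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) == 0L) next
      key <- tolower(trimws(m[2])); val <- m[3]
      if (grepl("^\\{", val) && !grepl("\\}", val)) { open <- TRUE; buf <- val; next }
      out[[key]] <- val
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { open <- FALSE; out[[key]] <- buf }
    }
  }
  out
}

envi_list <- function(x) {
  if (is.null(x)) return(NULL)
  x <- gsub("[{}]", "", x)
  trimws(strsplit(x, ",")[[1]])
}

write_envi <- function(values, path, dtype = "float64", wavelengths = NULL,
                       class_names = NULL, extra = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  d <- dim(values)
  code <- switch(dtype, uint8 = 1L, int16 = 2L, int32 = 3L,
                 float32 = 4L, float64 = 5L, uint16 = 12L,
                 abort(paste("unsupported ENVI dtype:", dtype), "bad_value"))
  tt <- .envi_types[[as.character(code)]]
  hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           sprintf("file type = %s",
                   if (is.null(class_names)) "ENVI Standard" else "ENVI Classification"),
           sprintf("data type = %d", code),
           "interleave = bsq",
           "byte order = 0")
  if (!is.null(wavelengths))
    hdr <- c(hdr, "wavelength units = Nanometers",
             paste0("wavelength = {", paste(format(wavelengths, trim = TRUE), collapse = ", "), "}"))
  if (!is.null(class_names))
    hdr <- c(hdr, sprintf("classes = %d", length(class_names)),
             paste0("class names = {", paste(class_names, collapse = ", "), "}"))
  if (!is.null(extra)) hdr <- c(hdr, extra)
  ok <- tryCatch({ writeLines(hdr, hdr_path); TRUE }, error = function(e) FALSE)
  if (!ok) abort(paste("cannot write", hdr_path), "unwritable")
  # BSQ, sample (col) fastest: permute (row, col, band) -> (col, row, band)
  v <- aperm(values, c(2L, 1L, 3L))
  con <- tryCatch(file(path, "wb"), error = function(e) abort(paste("cannot write", path), "unwritable"))
  on.exit(close(con))
  if (tt$what == "integer") {
    writeBin(as.integer(round(as.vector(v))), con, size = tt$size, endian = "little")
  } else {
    writeBin(as.double(as.vector(v)), con, size = tt$size, endian = "little")
  }
  invisible(path)
}

read_envi <- function(path) {
  hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  if (!file.exists(path)) abort(paste("no such file:", path), "missing_file")
  if (!file.exists(hdr_path)) abort(paste("no ENVI header:", hdr_path), "missing_file")
  h <- parse_envi_header(hdr_path)
  ns <- as.integer(h$samples); nl <- as.integer(h$lines); nb <- as.integer(h$bands)
  if (anyNA(c(ns, nl, nb)) || nb < 1L || ns < 1L || nl < 1L)
    abort("ENVI header has invalid dimensions", "bad_header")
  tt <- .envi_types[[h[["data type"]]]]
  if (is.null(tt)) abort(paste("unsupported ENVI data type:", h[["data type"]]), "bad_header")
  n <- as.double(ns) * nl * nb
  if (file.size(path) != n * tt$size)
    abort(sprintf("ENVI payload (%d bytes) disagrees with header dimensions (%d x %d x %d, %d expected bytes)",
                  file.size(path), nl, ns, nb, n * tt$size), "bad_dims")
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, tt$what, n = n, size = tt$size, signed = tt$signed, endian = endian)
  il <- tolower(h$interleave %||% "bsq")
  arr <- switch(il,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3L, 2L, 1L)),
    abort(paste("unsupported interleave:", il), "bad_header"))
  list(values = arr, header = h, dn_max = tt$max)
}

# ---- public readers / writers ------------------------------------------------

#' Read a hyperspectral cube from ENVI or TIFF
#'
#' ENVI files (`.dat`/`.img`/`.envi` beside a text `.hdr`) preserve band
#' wavelengths; plain multi-directory TIFF (one directory per band) is also
#' accepted. Integer digital numbers are divided by the data type's declared
#' maximum so that values land in \[0, 1\].
#'
#' @param path path to the binary/TIFF file.
#' @return a [hyperspectral_cube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path), "missing_file")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    bands <- list()
    for (p in pages) {
      if (is.matrix(p)) bands <- c(bands, list(p))
      else for (c in seq_len(dim(p)[3])) bands <- c(bands, list(p[, , c]))
    }
    if (length(bands) == 0L) abort("TIFF contains no bands", "bad_header")
    arr <- array(unlist(bands), c(dim(bands[[1]]), length(bands)))
    return(hyperspectral_cube(arr))
  }
  e <- read_envi(path)
  vals <- e$values
  if (!is.na(e$dn_max)) vals <- vals / e$dn_max
  wl <- suppressWarnings(as.numeric(envi_list(e$header$wavelength)))
  if (length(wl) == 0L || anyNA(wl)) wl <- NULL
  hyperspectral_cube(vals, wavelengths_nm = wl)
}

#' Write a hyperspectral cube
#'
#' ENVI (`.dat` + `.hdr`, float64, band-sequential) or TIFF (float32, one
#' directory per band; wavelengths are not persisted in TIFF).
#'
#' @param cube a [hyperspectral_cube()].
#' @param path output path; format chosen by extension.
#' @export
write_cube <- function(cube, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    d <- dim(cube$values)
    bands <- lapply(seq_len(d[3]), function(b) cube$values[, , b])
    tiff::writeTIFF(bands, path, bits.per.sample = 32)
  } else {
    write_envi(cube$values, path, dtype = "float64", wavelengths = cube$wavelengths_nm)
  }
  invisible(path)
}

#' Write / read a label map
#'
#' ENVI classification format: pixels are stored as bytes with 0 = nodata and
#' 1..K matching the legend, whose class names are persisted in the header.
#' The round trip is value-exact.
#'
#' @param map a [label_map()].
#' @param path output path (`.dat`; a `.hdr` is written alongside).
#' @export
write_label_map <- function(map, path) {
  if (length(map$legend) < 1L) abort("legend must be non-empty", "bad_legend")
  v <- map$values
  v[is.na(v)] <- 0L
  write_envi(v, path, dtype = if (length(map$legend) < 255L) "uint8" else "int16",
             class_names = c("nodata", map$legend))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  e <- read_envi(path)
  cls <- envi_list(e$header[["class names"]])
  if (is.null(cls) || length(cls) < 2L)
    abort("label map file carries no class names", "bad_legend")
  v <- e$values[, , 1L]
  storage.mode(v) <- "integer"
  v[v == 0L] <- NA_integer_
  label_map(v, legend = cls[-1L])
}

#' Write / read a guidance image
#'
#' PNG stores 8-bit channels (adequate for camera RGB); TIFF stores float32.
#'
#' @param guidance a [guidance_image()].
#' @param path output path, `.png` or `.tif`.
#' @export
write_guidance <- function(guidance, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(guidance$values, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(guidance$values, path, bits.per.sample = 32)
  else abort(paste("unsupported guidance format:", ext), "bad_value")
  invisible(path)
}

#' @rdname write_guidance
#' @param provenance provenance tag to attach on read.
#' @export
read_guidance <- function(path, provenance = "rgb_resampled") {
  if (!file.exists(path)) abort(paste("no such file:", path), "missing_file")
  ext <- tolower(tools::file_ext(path))
  v <- if (ext == "png") png::readPNG(path)
       else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else abort(paste("unsupported guidance format:", ext), "bad_value")
  if (length(dim(v)) == 3L && dim(v)[3] == 4L) v <- v[, , 1:3]  # drop alpha
  guidance_image(clip01(v), provenance = provenance)
}

#' Load a pixel sample table from CSV
#'
#' Expected columns: `row`, `col`, `class`, `role`. `class` may hold class
#' names (resolved against `legend`) or 1-based integer ids. Coordinates are
#' 1-based and bounds-checked against `raster_shape`; duplicate coordinates
#' are rejected.
#'
#' @param path CSV path.
#' @param raster_shape `c(H, W)` of the raster the samples index into.
#' @param legend class names; defaults to the sorted unique names in the file.
#' @return a [sample_set()].
#' @export
load_samples <- function(path, raster_shape, legend = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path), "missing_file")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "class", "role")
  if (!all(need %in% names(df)))
    abort(paste("sample CSV needs columns:", paste(need, collapse = ", ")), "bad_samples")
  if (is.numeric(df$class)) {
    if (is.null(legend)) legend <- paste0("class_", sort(unique(df$class)))
    class_id <- as.integer(df$class)
  } else {
    if (is.null(legend)) legend <- sort(unique(df$class))
    class_id <- match(df$class, legend)
    if (anyNA(class_id))
      abort(paste("unknown class name(s):",
                  paste(unique(df$class[is.na(class_id)]), collapse = ", ")), "bad_samples")
  }
  sample_set(data.frame(row = df$row, col = df$col, class_id = class_id, role = df$role),
             legend = legend, raster_shape = raster_shape)
}

#' @rdname load_samples
#' @param samples a [sample_set()] to write.
#' @export
write_samples <- function(samples, path) {
  legend <- attr(samples, "legend")
  out <- data.frame(row = samples$row, col = samples$col,
                    class = legend[samples$class_id], role = samples$role)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
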