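test_that("ENVI cube round-trips exactly, preserving wavelengths and orientation", {
  set.seed(42)
  wl <- seq(450, 950, length.out = 5)
  vals <- array(runif(12 * 10 * 5), c(12, 10, 5))
  vals[1, 1, 1] <- 0.111; vals[12, 1, 1] <- 0.222; vals[1, 10, 1] <- 0.333
  cube <- hyperspectral_cube(vals, wavelengths_nm = wl)
  path <- file.path(tempdir(), "cube_rt.dat")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$values, cube$values)
  expect_equal(back$wavelengths_nm, wl)
  # corner convention: row 1 = top survives the round trip
  expect_identical(back$values[1, 1, 1], 0.111)
  expect_identical(back$values[12, 1, 1], 0.222)
  expect_identical(back$values[1, 10, 1], 0.333)
})

test_that("a 125-band cube and a single-band cube load with the right band counts", {
  p125 <- file.path(tempdir(), "cube125.dat")
  write_cube(hyperspectral_cube(array(runif(8 * 8 * 125), c(8, 8, 125)),
                                wavelengths_nm = seq(450, 950, by = 4)[1:125]), p125)
  expect_equal(dim(read_cube(p125)$values)[3], 125L)
  p1 <- file.path(tempdir(), "cube1.dat")
  write_cube(hyperspectral_cube(matrix(runif(30), 5, 6)), p1)
  expect_equal(dim(read_cube(p1)$values), c(5L, 6L, 1L))
})

test_that("malformed or absent ENVI inputs raise distinct conditions", {
  expect_error(read_cube(file.path(tempdir(), "nope.dat")),
               class = "crownepf_missing_file")
  # header advertises more bands than the payload holds
  p <- file.path(tempdir(), "trunc.dat")
  write_cube(hyperspectral_cube(array(runif(6 * 6 * 10), c(6, 6, 10))), p)
  hdr <- readLines(paste0(tools::file_path_sans_ext(p), ".hdr"))
  # shrink the payload by one band's worth of bytes
  sz <- file.size(p)
  con <- file(p, "r+b"); truncate_at <- sz - 6 * 6 * 8
  raw <- readBin(con, "raw", truncate_at); close(con)
  writeBin(raw, p)
  expect_error(read_cube(p), class = "crownepf_bad_dims")
})

test_that("integer DN cubes are scaled to [0, 1] by the type maximum", {
  p <- file.path(tempdir(), "dn.dat")
  crownepf:::write_envi(array(c(0, 1000, 65535, 40000, 20000, 3), c(3, 2, 1)),
                        p, dtype = "uint16")
  v <- read_cube(p)$values
  expect_gte(min(v), 0); expect_lte(max(v), 1)
  expect_equal(v[3, 1, 1], 1)            # 65535 / 65535
  expect_equal(v[2, 1, 1], 1000 / 65535)
})

test_that("BIL and BIP interleaves decode to the same array as BSQ", {
  set.seed(3)
  arr <- array(runif(4 * 5 * 3), c(4, 5, 3))
  base <- file.path(tempdir(), "il_bsq.dat")
  crownepf:::write_envi(arr, base, dtype = "float64")
  ref <- read_cube(base)$values
  hdr_of <- function(p) paste0(tools::file_path_sans_ext(p), ".hdr")
  for (il in c("bil", "bip")) {
    p <- file.path(tempdir(), paste0("il_", il, ".dat"))
    v <- if (il == "bil") aperm(arr, c(2, 3, 1)) else aperm(arr, c(3, 2, 1))
    writeBin(as.double(as.vector(v)), p, size = 8, endian = "little")
    hdr <- readLines(hdr_of(base))
    writeLines(sub("interleave = bsq", paste("interleave =", il), hdr), hdr_of(p))
    expect_identical(read_cube(p)$values, ref, label = il)
  }
})

test_that("TIFF cubes round-trip within float32 precision", {
  cube <- hyperspectral_cube(array(runif(9 * 7 * 6), c(9, 7, 6)))
  p <- file.path(tempdir(), "cube.tif")
  write_cube(cube, p)
  expect_lt(max(abs(read_cube(p)$values - cube$values)), 1e-6)
})

test_that("label maps round-trip exactly with legend and nodata", {
  v <- matrix(sample(1:4, 60, replace = TRUE), 6, 10)
  v[2, 3] <- NA
  map <- label_map(v, c("bare_land", "understory_vegetation", "shadow", "damaged_pine"))
  p <- file.path(tempdir(), "labels.dat")
  write_label_map(map, p)
  back <- read_label_map(p)
  expect_identical(back$values, map$values)
  expect_identical(back$legend, map$legend)
  expect_true(is.na(back$values[2, 3]))
})

test_that("label map construction enforces the legend contract", {
  expect_error(label_map(matrix(1L, 2, 2), character(0)), class = "crownepf_bad_legend")
  expect_error(label_map(matrix(1L, 2, 2), "only_one"), class = "crownepf_bad_legend")
  expect_error(label_map(matrix(5L, 2, 2), c("a", "b")), class = "crownepf_bad_value")
})

test_that("guidance images round-trip through PNG (8-bit) and TIFF (float)", {
  g <- guidance_image(array(runif(8 * 8 * 3), c(8, 8, 3)), "synthetic")
  p_png <- file.path(tempdir(), "g.png")
  write_guidance(g, p_png)
  expect_lt(max(abs(read_guidance(p_png)$values - g$values)), 1 / 255 + 1e-9)
  p_tif <- file.path(tempdir(), "g.tif")
  write_guidance(g, p_tif)
  expect_lt(max(abs(read_guidance(p_tif)$values - g$values)), 1e-6)
  expect_error(guidance_image(matrix(2, 3, 3), "synthetic"), class = "crownepf_bad_value")
})

test_that("sample tables load with bounds checks, duplicate and class validation", {
  df <- data.frame(row = c(1, 2, 3, 4), col = c(1, 1, 2, 2),
                   class = c("a", "a", "b", "b"),
                   role = c("training", "verification", "training", "verification"))
  p <- file.path(tempdir(), "samples.csv")
  write.csv(df, p, row.names = FALSE)
  ss <- load_samples(p, c(4, 2))
  expect_s3_class(ss, "sample_set")
  expect_identical(attr(ss, "legend"), c("a", "b"))

  write.csv(rbind(df, df[1, ]), p, row.names = FALSE)
  expect_error(load_samples(p, c(4, 2)), class = "crownepf_bad_samples")

  bad <- df; bad$row[1] <- 5   # == H + 1: outside closed 1-based bounds
  write.csv(bad, p, row.names = FALSE)
  expect_error(load_samples(p, c(4, 2)), class = "crownepf_bad_samples")

  write.csv(df, p, row.names = FALSE)
  expect_error(load_samples(p, c(4, 2), legend = c("a", "x")),
               class = "crownepf_bad_samples")
})

test_that("samples survive a CSV round trip and the 3:1 splitter is stratified", {
  scn <- small_scene()
  p <- file.path(tempdir(), "scene_samples.csv")
  write_samples(scn$samples, p)
  back <- load_samples(p, dim(scn$labels$values), legend = attr(scn$samples, "legend"))
  expect_equal(nrow(back), nrow(scn$samples))
  resplit <- split_samples(back, train_fraction = 0.75, seed = 9)
  tab <- table(resplit$class_id, resplit$role)
  expect_true(all(abs(tab[, "training"] / rowSums(tab) - 0.75) < 0.01))
})
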