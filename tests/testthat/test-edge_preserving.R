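test_that("PCA false colour spans the dominant band subspace and is deterministic", {
  set.seed(11)
  h <- 24; w <- 24
  patterns <- list(matrix(rnorm(h * w), h, w), matrix(rnorm(h * w), h, w),
                   matrix(rnorm(h * w), h, w))
  loadings <- matrix(rnorm(3 * 12), 3, 12)
  vals <- array(0, c(h, w, 12))
  for (b in 1:12) {
    for (k in 1:3) vals[, , b] <- vals[, , b] + patterns[[k]] * loadings[k, b]
    vals[, , b] <- vals[, , b] + rnorm(h * w, 0, 1e-4)
  }
  cube <- hyperspectral_cube(vals)
  fc <- pca_false_color(cube)
  # each generating pattern is reconstructed from the 3 channels with R^2 > 0.99
  ch <- matrix(fc$values, h * w, 3)
  for (k in 1:3) {
    fit <- lm.fit(cbind(1, ch), as.vector(patterns[[k]]))
    r2 <- 1 - sum(fit$residuals^2) / sum((patterns[[k]] - mean(patterns[[k]]))^2)
    expect_gt(r2, 0.99)
  }
  expect_identical(fc$values, pca_false_color(cube)$values)  # deterministic sign rule
  expect_gte(min(fc$values), 0); expect_lte(max(fc$values), 1)

  expect_error(pca_false_color(hyperspectral_cube(array(0.5, c(4, 4, 5)))),
               class = "crownepf_bad_value")
  expect_error(pca_false_color(hyperspectral_cube(array(runif(32), c(4, 4, 2)))),
               class = "crownepf_bad_dims")
})

test_that("guidance resampling hits the target grid and fixes constants", {
  set.seed(12)
  g <- guidance_image(array(runif(40 * 40 * 3), c(40, 40, 3)), "rgb_resampled")
  out <- resample_guidance(g, c(20, 20))
  expect_equal(dim(out$values), c(20L, 20L, 3L))
  expect_equal(resample_guidance(g, c(40, 40))$values, g$values, tolerance = 1e-12)
  const <- guidance_image(array(0.4, c(30, 30, 3)), "rgb_resampled")
  expect_true(all(abs(resample_guidance(const, c(11, 17))$values - 0.4) < 1e-12))
  expect_error(resample_guidance(g, c(0, 10)), class = "crownepf_bad_dims")
})

test_that("the JBF is a convex combination that fixes constants and respects bounds", {
  set.seed(13)
  g <- matrix(runif(14 * 14), 14, 14)
  const <- matrix(0.37, 14, 14)
  for (sd_ in c(1, 2)) for (sr in c(0.05, 0.4))
    expect_true(all(abs(joint_bilateral_filter(const, g, sd_, sr) - 0.37) < 1e-12))
  p <- matrix(runif(14 * 14), 14, 14)
  q <- joint_bilateral_filter(p, g, 1.5, 0.1)
  expect_gte(min(q), min(p)); expect_lte(max(q), max(p))
  expect_error(joint_bilateral_filter(p, g[1:10, ], 1, 0.1), class = "crownepf_bad_dims")
  expect_error(joint_bilateral_filter(p, g, 0, 0.1), class = "crownepf_bad_value")
  expect_error(joint_bilateral_filter(p, g, 1, -1), class = "crownepf_bad_value")
})

test_that("both filters commute with adding a constant to the input map", {
  set.seed(14)
  p <- matrix(runif(16 * 16), 16, 16)
  g <- matrix(runif(16 * 16), 16, 16)
  expect_lt(max(abs(joint_bilateral_filter(p + 0.3, g, 1, 0.1) -
                    (joint_bilateral_filter(p, g, 1, 0.1) + 0.3))), 1e-10)
  expect_lt(max(abs(guided_filter(p + 0.3, g, 2, 0.01) -
                    (guided_filter(p, g, 2, 0.01) + 0.3))), 1e-10)
})

test_that("in the wide-range limit the JBF collapses to the spatial Gaussian blur", {
  set.seed(15)
  p <- matrix(runif(18 * 18), 18, 18)
  g <- matrix(runif(18 * 18), 18, 18)
  for (sd_ in c(1, 2)) {
    blur <- crownepf:::gaussian_blur(p, sd_ / sqrt(2), radius = ceiling(3 * sd_))
    expect_lt(max(abs(joint_bilateral_filter(p, g, sd_, 1e6, spatial_squared = TRUE) -
                      blur)), 1e-9)
  }
})

test_that("guided filter limits: self-guidance identity and regularizer-dominated box averaging", {
  set.seed(16)
  g <- matrix(runif(15 * 15), 15, 15)
  expect_lt(max(abs(guided_filter(g, g, 2, 0) - g)), 1e-10)
  p <- matrix(runif(15 * 15), 15, 15)
  # as epsilon -> Inf, a -> 0 and b -> window mean, so the output is the box
  # mean of the window means: two cascaded (2r+1) box means, guidance-free
  expect_lt(max(abs(guided_filter(p, g, 2, 1e9) - naive_box(naive_box(p, 2), 2))), 1e-6)
  g2 <- matrix(runif(15 * 15), 15, 15)
  expect_lt(max(abs(guided_filter(p, g, 2, 1e9) - guided_filter(p, g2, 2, 1e9))), 1e-6)
  expect_error(guided_filter(p, g, 0, 0.1), class = "crownepf_bad_value")
  expect_error(guided_filter(p, g[1:10, ], 1, 0.1), class = "crownepf_bad_dims")
})

test_that("vectorized filters equal the literal brute-force implementations", {
  set.seed(17)
  for (t in 1:4) {
    p <- matrix(runif(256), 16, 16)
    g1 <- matrix(runif(256), 16, 16)
    g3 <- array(runif(256 * 3), c(16, 16, 3))
    expect_lt(max(abs(joint_bilateral_filter(p, g1, 1, 0.1) - jbf_oracle(p, g1, 1, 0.1))),
              1e-10)
    expect_lt(max(abs(joint_bilateral_filter(p, g3, 2, 0.2) - jbf_oracle(p, g3, 2, 0.2))),
              1e-10)
    expect_lt(max(abs(guided_filter(p, g1, 2, 0.01) - gf_oracle(p, g1, 2, 0.01))),
              1e-10)
  }
})

test_that("filter_stack treats layers independently, fixes constants, keeps [0,1]", {
  set.seed(18)
  vals <- array(runif(12 * 12 * 4), c(12, 12, 4))
  stack <- probability_stack(vals, paste0("c", 1:4))
  g <- guidance_image(array(runif(12 * 12 * 3), c(12, 12, 3)), "synthetic")
  out <- filter_stack(stack, g, "jbf", list(sigma_d = 1, sigma_r = 0.1))
  for (k in 1:4)
    expect_equal(out$values[, , k],
                 joint_bilateral_filter(vals[, , k], g$values, 1, 0.1))
  out_gf <- filter_stack(stack, g, "gf", list(r = 1, epsilon = 0.01))
  gl <- crownepf:::luminance(g$values)
  for (k in 1:4)
    expect_equal(out_gf$values[, , k],
                 pmin(pmax(guided_filter(vals[, , k], gl, 1, 0.01), 0), 1))
  const <- probability_stack(array(rep(c(0.1, 0.2, 0.3, 0.4), each = 144),
                                   c(12, 12, 4)), paste0("c", 1:4))
  cf <- filter_stack(const, g, "gf", list(r = 2, epsilon = 0.01))
  expect_lt(max(abs(cf$values - const$values)), 1e-10)
  expect_error(filter_stack(probability_stack(array(0.5, c(5, 5, 1)), "a"), g, "jbf"),
               class = "crownepf_bad_dims")
})

test_that("filtering pulls a displaced step edge onto the guidance edge", {
  # complementary step maps with the class boundary at column 8; the guidance
  # puts the true edge at column 9 — the fused edge should move to it
  h <- 16; w <- 16
  p1 <- matrix(0, h, w); p1[, 1:8] <- 1
  stack <- probability_stack(array(c(p1, 1 - p1), c(h, w, 2)), c("a", "b"))
  g <- matrix(0, h, w); g[, 1:9] <- 1
  for (method in c("jbf", "gf")) {
    params <- if (method == "jbf") list(sigma_d = 2, sigma_r = 0.1)
              else list(r = 2, epsilon = 0.01)
    fused <- fuse_max_probability(
      filter_stack(stack, guidance_image(array(g, c(h, w, 3)), "synthetic"),
                   method, params))
    edge_cols <- apply(fused$values, 1, function(r) max(which(r == 1L)))
    expect_true(all(edge_cols == 9L), label = method)
  }
})

test_that("on a clean step instance MSSIM decays as either filter widens", {
  # the module-level edge-preservation trend: a noise-free step filtered with
  # growing sigma_d (JBF) or r (GF) drifts away from the sharp guidance
  h <- 32; w <- 32
  p <- matrix(0, h, w); p[, 1:16] <- 1
  g <- p
  ms_jbf <- sapply(1:4, function(sd_)
    mssim(g, joint_bilateral_filter(p, g + 0.0, sd_, 0.4)))
  expect_true(all(diff(ms_jbf) <= 1e-12))
  ms_gf <- sapply(c(1, 2, 4, 8), function(r) mssim(g, guided_filter(p, g, r, 0.16)))
  expect_true(all(diff(ms_gf) <= 1e-12))
})
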