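test_that("equal-width discretization matches hand binning", {
  v <- toy_volume(c(0, 1, 2, 3))
  m <- full_mask(c(4, 1, 1))
  expect_equal(discretize(v, m, 2)$levels[, 1, 1], c(1L, 1L, 2L, 2L))

  v2 <- toy_volume(c(0, 5, 10, 16))
  expect_equal(discretize(v2, m, 16)$levels[, 1, 1], c(1L, 6L, 11L, 16L))

  const <- toy_volume(rep(7, 4))
  expect_true(all(discretize(const, m, 32)$levels[m$values] == 1L))

  expect_error(discretize(v, voxel_mask(array(FALSE, c(4, 1, 1))), 8), "empty")
})

test_that("shape features match analytic solids", {
  single <- voxel_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)))
  sf1 <- shape_features(single)
  expect_equal(unname(sf1["shape_volume_mm3"]), 1)

  sf2 <- shape_features(sphere_mask(10))
  expect_gt(unname(sf2["shape_sphericity"]), 0.95)
  expect_lt(unname(sf2["shape_sphericity"]), 1.05)
  expect_lt(abs(sf2[["shape_volume_mm3"]] - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)
  expect_lt(abs(sf2[["shape_surface_area_mm2"]] - 4 * pi * 100) / (4 * pi * 100),
            0.05)
  expect_lt(abs(sf2[["shape_max_diameter_mm"]] - 20), 0.5)

  sf3 <- shape_features(ellipsoid_mask(c(20, 10, 10)))
  expect_lt(abs(sf3[["shape_elongation"]] - 0.5), 0.03)
  expect_lt(abs(sf3[["shape_flatness"]] - 0.5), 0.03)

  expect_error(shape_features(voxel_mask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("ellipsoid mask volume tracks (4/3) pi abc within 5%", {
  for (axes in list(c(10, 10, 10), c(14, 11, 10), c(18, 12, 10))) {
    m <- ellipsoid_mask(axes)
    va <- 4 / 3 * pi * prod(axes)
    expect_lt(abs(sum(m$values) - va) / va, 0.05)
  }
})

test_that("first-order features match hand computations and conventions", {
  m <- full_mask(c(4, 1, 1))
  fo <- first_order_features(toy_volume(c(1, 2, 3, 4)), m)
  expect_equal(unname(fo["fo_mean"]), 2.5)
  expect_equal(unname(fo["fo_range"]), 3)

  m5 <- full_mask(c(5, 1, 1))
  fo5 <- first_order_features(toy_volume(c(1, 2, 2, 3, 4)), m5)
  expect_equal(unname(fo5["fo_energy"]), 34)

  foc <- first_order_features(toy_volume(rep(3, 5)), m5)
  expect_equal(unname(foc[c("fo_variance", "fo_entropy", "fo_skewness",
                            "fo_kurtosis")]), c(0, 0, 0, 0))
  expect_equal(unname(foc["fo_uniformity"]), 1)
})

test_that("constant regions give degenerate-matrix texture conventions", {
  v <- image_volume(array(5, c(4, 4, 4)))
  tf <- texture_features(discretize(v, full_mask(c(4, 4, 4)), 16))
  for (agg in c("mean", "range", "merged")) {
    expect_equal(unname(tf[paste0("glcm_contrast_", agg)]), 0)
    expect_equal(unname(tf[paste0("glcm_joint_entropy_", agg)]), 0)
  }
  expect_equal(unname(tf["glcm_joint_energy_merged"]), 1)
})

test_that("checkerboard co-occurrence contrast is 1 along the in-plane offset", {
  chk <- array(0, c(4, 4, 1))
  chk[] <- (row(chk[, , 1]) + col(chk[, , 1])) %% 2
  q <- discretize(image_volume(chk), full_mask(c(4, 4, 1)), 2)
  counts <- radioimmune:::`.glcm_counts`(q$levels, dim(q$levels), 2L)
  # offset (0,1,0) is the second direction; all 12 pairs differ by one level
  M <- counts[, , 2]
  P <- M / sum(M)
  contrast <- sum((row(P) - col(P))^2 * P)
  expect_equal(contrast, 1)
  expect_equal(sum(M), 24)  # 12 pairs, symmetric accumulation
})

test_that("merged co-occurrence matrix is symmetric and rows sum to 1", {
  q <- random_quantized(c(6, 6, 6), 4, seed = 5)
  counts <- radioimmune:::`.glcm_counts`(q$levels, dim(q$levels), 4L)
  merged <- apply(counts, c(1, 2), sum)
  expect_equal(merged, t(merged))
  expect_equal(sum(merged / sum(merged)), 1)
})

test_that("single-voxel regions return zeroed texture with a degenerate flag", {
  q <- discretize(toy_volume(5), full_mask(c(1, 1, 1)), 16)
  tf <- texture_features(q)
  expect_true(all(tf == 0))
  expect_true(isTRUE(attr(tf, "degenerate")))
})

test_that("every texture statistic equals the brute-force oracle on small grids", {
  cases <- list(list(dims = c(5, 4, 3), G = 3, seed = 1),
                list(dims = c(4, 4, 4), G = 4, seed = 2),
                list(dims = c(8, 7, 6), G = 4, seed = 3),
                list(dims = c(6, 6, 1), G = 2, seed = 4))
  for (cs in cases) {
    q <- random_quantized(cs$dims, cs$G, cs$seed)
    got <- texture_features(q)
    want <- oracle_texture_features(q$levels, cs$G, q$n_voxels)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-10,
                 info = paste("seed", cs$seed))
  }
})

test_that("texture features are invariant to intensity shift and scale", {
  set.seed(11)
  dims <- c(6, 6, 6)
  vals <- rnorm(prod(dims))
  m <- full_mask(dims)
  f1 <- texture_features(discretize(image_volume(array(vals, dims)), m, 8))
  f2 <- texture_features(discretize(image_volume(array(3 * vals + 100, dims)), m, 8))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("direction-mean GLCM statistics are invariant to 90-degree rotation", {
  set.seed(12)
  dims <- c(5, 5, 5)
  vals <- array(rnorm(prod(dims)), dims)
  rot <- aperm(vals[, dims[2]:1, ], c(2, 1, 3))  # 90 deg about z
  m <- full_mask(dims)
  f1 <- texture_features(discretize(image_volume(vals), m, 4))
  f2 <- texture_features(discretize(image_volume(rot), m, 4))
  mean_feats <- grep("^glcm_.*_mean$", names(f1), value = TRUE)
  expect_equal(f1[mean_feats], f2[mean_feats], tolerance = 1e-10)
})

test_that("the reference inventory yields 584 features with conserved family counts", {
  cfg <- synthetic_config(seed = 21)
  ph <- generate_phantom(list(lymphoid_latent = 0.3, myeloid_latent = -0.1),
                         list(semi_axes = c(8, 7, 6), spacing = c(1, 1, 1)),
                         seed = 77, config = cfg)
  pair <- build_peritumoral_ring(ph$mask)
  fv <- extract_feature_vector(ph$volume, pair)
  expect_length(fv, 584)
  for (rg in c("intra_", "peri_")) {
    rg_names <- grep(paste0("^", rg), names(fv), value = TRUE)
    expect_length(rg_names, 292)
    expect_length(grep("_shape_", rg_names), 8)
    expect_length(grep("_fo_", rg_names), 14)
    expect_length(grep("_b(16|32|64)_", rg_names), 270)
  }
  expect_false(any(duplicated(names(fv))))
  expect_true(all(is.finite(fv)))
  # determinism
  fv2 <- extract_feature_vector(ph$volume, pair)
  expect_identical(fv, fv2)
})

test_that("ICC(2,1) matches the mean-squares formula and its limits", {
  # identical raters
  r <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_single(r)$icc, 1)

  # worked 4-patient 2-rater table against a hand ANOVA oracle
  tab <- cbind(c(9, 6, 8, 7), c(2, 1, 4, 1))
  n <- 4; k <- 2
  grand <- mean(tab)
  msr <- k * sum((rowMeans(tab) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(tab) - grand)^2) / (k - 1)
  sse <- sum((tab - outer(rowMeans(tab), rep(1, k)) -
                outer(rep(1, n), colMeans(tab)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_single(tab)$icc, want, tolerance = 1e-12)

  # independent noise -> ICC near 0
  set.seed(31)
  noise <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_single(noise)$icc), 0.1)

  # zero between-patient variance flag
  z <- icc_single(matrix(5, 4, 2))
  expect_equal(z$icc, 0)
  expect_equal(z$flag, "zero_between_patient_variance")
})

test_that("the ICC table covers every feature and feeds the filter", {
  set.seed(32)
  nf <- 5
  truth <- matrix(rnorm(20 * nf), 20, nf)
  arr <- array(NA_real_, c(20, 2, nf),
               dimnames = list(NULL, NULL, paste0("f", 1:nf)))
  arr[, 1, ] <- truth + rnorm(20 * nf, 0, 0.1)
  arr[, 2, ] <- truth + rnorm(20 * nf, 0, 0.1)
  arr[, 2, 5] <- rnorm(20)  # one irreproducible feature
  tab <- compute_icc(arr)
  expect_equal(nrow(tab), nf)
  kept <- icc_filter(tab, threshold = 0.75)
  expect_true(all(paste0("f", 1:4) %in% kept))
  expect_false("f5" %in% kept)
})
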