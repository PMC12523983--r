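# Per-frame feature oracles: closed-form geometry on known masks, brute-force
# pixel enumeration on random masks, invariances, and texture conventions.

square_mask <- function(side) matrix(TRUE, side, side)

test_that("10x10 square matches the closed-form geometry oracle", {
  inst <- make_instance(square_mask(10))
  v <- size_shape_features(inst)
  expect_equal(unname(v["Area"]), 100)
  expect_equal(unname(v["Perimeter"]), 40)
  expect_equal(unname(v["AspectRatio"]), 1)
  expect_equal(unname(v["Extent"]), 1)
  expect_equal(unname(v["Circularity"]), 4 * pi * 100 / 40^2)
  expect_equal(unname(v["Eccentricity"]), 0)
  expect_equal(unname(v["Solidity"]), 1)
  expect_equal(unname(v["BoundingBoxArea"]), 100)
  expect_equal(unname(v["EquivalentDiameter"]), 2 * sqrt(100 / pi))
})

test_that("single-pixel mask uses the degenerate conventions", {
  inst <- make_instance(matrix(TRUE, 1, 1))
  v <- size_shape_features(inst)
  expect_equal(unname(v["Area"]), 1)
  expect_equal(unname(v["Perimeter"]), 4)
  expect_equal(unname(v["AspectRatio"]), 1)
  expect_equal(unname(v["Eccentricity"]), 0)
  expect_equal(unname(v["MinorAxisLength"]), 0)
})

random_blob <- function(seed, n = 12) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  cx <- runif(1, 4, n - 4); cy <- runif(1, 4, n - 4)
  r <- runif(1, 2, 3.5)
  for (i in 1:n) for (j in 1:n) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  }
  m
}

test_that("area, perimeter and moments agree with brute-force enumeration", {
  for (seed in 1:10) {
    m <- random_blob(seed)
    inst <- make_instance(m)
    v <- size_shape_features(inst)
    expect_equal(unname(v["Area"]), sum(m))
    # brute-force perimeter: scan every pixel, count exposed 4-neighbour edges
    per <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (!m[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        outside <- ii < 1 || ii > nrow(m) || jj < 1 || jj > ncol(m)
        if (outside || !m[ii, jj]) per <- per + 1
      }
    }
    expect_equal(unname(v["Perimeter"]), per)
    # brute-force moment ellipse from raw pixel coordinates
    ys <- which(m, arr.ind = TRUE)[, 1] - 1
    xs <- which(m, arr.ind = TRUE)[, 2] - 1
    C <- stats::cov.wt(cbind(xs, ys), method = "ML")$cov
    ev <- sort(eigen(C, symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(unname(v["MajorAxisLength"]), 4 * sqrt(max(ev[1], 0)),
                 tolerance = 1e-10)
    expect_equal(unname(v["MinorAxisLength"]), 4 * sqrt(max(ev[2], 0)),
                 tolerance = 1e-10)
  }
})

test_that("size/shape features are invariant to translation and 90-degree rotation", {
  for (seed in 1:5) {
    m <- random_blob(seed)
    set.seed(seed + 100)
    texture <- runif(sum(m), 50, 200)
    base <- extract_frame_features(
      embedded_instance(m, at = c(3, 3), intensity_values = texture),
      solo_context(embedded_instance(m, at = c(3, 3)), diagonal = 10))
    shifted <- extract_frame_features(
      embedded_instance(m, at = c(8, 10), intensity_values = texture),
      solo_context(embedded_instance(m, at = c(8, 10)), diagonal = 10))
    expect_equal(base, shifted, tolerance = 1e-10)

    # rotation: compare the mask-derived features only (rotation permutes
    # pixel order, so rebuild the intensity patch consistently)
    inst_r <- make_instance(t(m)[ncol(m):1, , drop = FALSE])
    inst_0 <- make_instance(m)
    v0 <- size_shape_features(inst_0)
    vr <- size_shape_features(inst_r)
    expect_equal(v0[setdiff(names(v0), c("CurvatureMean", "CurvatureSD"))],
                 vr[setdiff(names(vr), c("CurvatureMean", "CurvatureSD"))],
                 tolerance = 1e-9)
    expect_equal(abs(v0["CurvatureMean"]), abs(vr["CurvatureMean"]),
                 tolerance = 1e-9)
    expect_equal(v0["CurvatureSD"], vr["CurvatureSD"], tolerance = 1e-9)
  }
})

test_that("GLCM texture is invariant under rotation of patch and mask", {
  # block-aligned crop (bounding box a multiple of the 4x4 block) so the
  # downsampled scales rotate cleanly with the patch
  m <- matrix(FALSE, 12, 12)
  m[, 6:7] <- TRUE
  m[6:7, ] <- TRUE
  m[2:5, 2:4] <- TRUE
  rot <- function(x) t(x)[ncol(x):1, , drop = FALSE]
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(runif(length(m), 0, 255), nrow(m), ncol(m))
    t0 <- texture_features(make_instance(m, img))
    t90 <- texture_features(make_instance(rot(m), rot(img)))
    expect_equal(t0, t90, tolerance = 1e-9)
  }
})

test_that("2x nearest-neighbour upscaling multiplies Area by exactly 4", {
  for (seed in 1:5) {
    m <- random_blob(seed)
    up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    a1 <- size_shape_features(make_instance(m))["Area"]
    a2 <- size_shape_features(make_instance(up))["Area"]
    expect_equal(unname(a2), 4 * unname(a1))
  }
})

test_that("checkerboard co-occurrence contrast matches the hand enumeration", {
  cb <- outer(1:8, 1:8, function(r, c) ifelse((r + c) %% 2 == 0, 100, 0))
  tx <- texture_features(make_instance(matrix(TRUE, 8, 8), cb))
  # horizontal/vertical offsets: every neighbour pair differs by 15 levels
  # (contrast 225 each); diagonal offsets pair equal values (contrast 0)
  expect_equal(unname(tx["Contrast_s1"]), (225 + 225 + 0 + 0) / 4)
})

test_that("constant-intensity cells take the zero-variance conventions", {
  tx <- texture_features(make_instance(matrix(TRUE, 6, 6),
                                       matrix(42, 6, 6)))
  expect_equal(unname(tx["IntensitySD_s1"]), 0)
  expect_equal(unname(tx["IntensityRange_s1"]), 0)
  expect_equal(unname(tx["IntensitySkewness_s1"]), 0)
  expect_equal(unname(tx["IntensityKurtosis_s1"]), 0)
  expect_equal(unname(tx["ASM_s1"]), 1)
  expect_equal(unname(tx["Contrast_s1"]), 0)
  expect_equal(unname(tx["GLCMEntropy_s1"]), 0)
  expect_equal(unname(tx["Correlation_s1"]), 0)
})

test_that("co-occurrence statistics are invariant under positive affine rescaling", {
  glcm_names <- paste0(rep(c("ASM", "Contrast", "Correlation", "GLCMVariance",
                             "Homogeneity", "SumAverage", "SumEntropy",
                             "GLCMEntropy", "Dissimilarity", "SumVariance"),
                           3),
                       "_", rep(c("s1", "s2", "s4"), each = 10))
  for (seed in 1:5) {
    m <- random_blob(seed)
    set.seed(seed)
    img <- matrix(runif(length(m), 0, 255), nrow(m), ncol(m))
    t0 <- texture_features(make_instance(m, img))
    t1 <- texture_features(make_instance(m, 2.5 * img + 40))
    expect_equal(t0[glcm_names], t1[glcm_names], tolerance = 1e-10)
  }
})

test_that("co-occurrence probabilities sum to 1 whenever a pair exists", {
  # direct check through glcm invariants exposed via statistics: a uniform
  # two-level patch has ASM + off-diagonal mass consistent with a probability
  # distribution; verify with a hand-built 2x2 patch
  patch <- matrix(c(0, 100, 0, 100), 2, 2)
  tx <- texture_features(make_instance(matrix(TRUE, 2, 2), patch))
  # with probabilities summing to 1, Homogeneity <= 1 and ASM <= 1
  expect_lte(unname(tx["ASM_s1"]), 1)
  expect_lte(unname(tx["Homogeneity_s1"]), 1)
  expect_gte(unname(tx["Homogeneity_s1"]), 0)
})

test_that("movement and density follow the stated conventions", {
  inst <- embedded_instance(square_mask(4), at = c(5, 5),
                            frame_dim = c(100, 100))
  # single cell: sentinel nearest-neighbour distance = image diagonal
  ctx <- solo_context(inst, diagonal = sqrt(2) * 100)
  v <- movement_density_features(inst, ctx)
  expect_equal(unname(v["DisplacementFromPrev"]), 0)
  expect_equal(unname(v["NeighbourCount"]), 0)
  expect_equal(unname(v["NearestNeighbourDistance"]), sqrt(2) * 100,
               tolerance = 1e-12)
  expect_equal(unname(v["LocalDensity"]), 0)

  # two-body case at distance 30
  cen <- inst$centroid
  ctx2 <- list(centroids = data.frame(x = c(cen["x"], cen["x"] + 30),
                                      y = c(cen["y"], cen["y"])),
               self = 1, prev_centroid = c(x = cen[["x"]] - 3,
                                           y = cen[["y"]] - 4),
               diagonal = sqrt(2) * 100, density_radius = 100)
  v2 <- movement_density_features(inst, ctx2)
  expect_equal(unname(v2["NeighbourCount"]), 1)
  expect_equal(unname(v2["NearestNeighbourDistance"]), 30)
  expect_equal(unname(v2["LocalDensity"]), 1 / 30)
  expect_equal(unname(v2["DisplacementFromPrev"]), 5)
})

test_that("the assembled frame vector is registry-ordered, named and deterministic", {
  inst <- embedded_instance(random_blob(4), at = c(4, 4))
  ctx <- solo_context(inst)
  v1 <- extract_frame_features(inst, ctx)
  v2 <- extract_frame_features(inst, ctx)
  expect_length(v1, 72)
  expect_identical(names(v1), feature_registry()$name)
  expect_identical(v1, v2)
})

test_that("disconnected masks reduce to the largest component with a warning", {
  lab <- matrix(0L, 12, 12)
  lab[2:5, 2:5] <- 1L
  lab[9:10, 9:10] <- 1L
  img <- matrix(100, 12, 12)
  expect_warning(inst <- cell_instance(img, lab, 1L), "disconnected")
  expect_equal(sum(inst$mask), 16)
})
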