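test_that("optical density is -log(v) with a 1e-3 floor, white maps to 0", {
  img <- array(c(1, 0.5, 1e-4, 0.1), dim = c(2, 2, 1))
  od <- od_transform(img)
  expect_equal(od[1, 1, 1], 0)
  expect_equal(od[2, 1, 1], -log(0.5))
  expect_equal(od[1, 2, 1], -log(1e-3))  # floored
  expect_error(od_transform(array(1.2, dim = c(1, 1, 1))), "\\[0, 1\\]")
})

test_that("OD normalization gives each channel zero mean and unit SD over tissue", {
  spot <- toy_spot()
  od <- od_transform(spot)
  mask <- od[, , 1] + od[, , 2] + od[, , 3] > 3 * 0.15
  norm <- normalize_od(od, mask)
  for (ch in 1:3) {
    expect_equal(mean(norm[, , ch][mask]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(norm[, , ch][mask]), 1, tolerance = 1e-12)
  }
})

test_that("normalization removes an additive per-channel stain shift", {
  spot <- toy_spot()
  shifted <- spot
  shifted[, , 1] <- pmin(pmax(shifted[, , 1] + 0.05, 0), 1)
  mask <- matrix(TRUE, dim(spot)[1], dim(spot)[2])
  n1 <- normalize_od(od_transform(spot), mask)
  # the shift acts on transmitted light, so post-OD it is approximately
  # additive in log space; standardization must cancel most of it
  n2 <- normalize_od(od_transform(shifted), mask)
  expect_lt(mean(abs(n1[, , 1] - n2[, , 1])), 0.15)
})

test_that("a constant channel normalizes to zeros with a warning", {
  od <- array(c(rep(1, 4), 1:4), dim = c(2, 2, 2))
  expect_warning(out <- normalize_od(od), "constant")
  expect_equal(out[, , 1], matrix(0, 2, 2))
})

test_that("color augmentation draws factors within the configured ranges", {
  spot <- toy_spot()
  set.seed(8)
  for (i in 1:20) {
    out <- augment_color(spot)
    f <- attr(out, "factors")
    expect_lte(abs(f[["brightness"]]), 0.02)
    expect_lte(abs(f[["contrast"]]), 0.05)
    expect_lte(abs(f[["saturation"]]), 0.20)
    expect_lte(abs(f[["hue"]]), 0.05)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("zero-range color augmentation is the identity", {
  spot <- toy_spot()
  out <- augment_color(spot, brightness = 0, contrast = 0, saturation = 0, hue = 0)
  expect_equal(as.vector(out), as.vector(spot), tolerance = 1e-12)
})

test_that("hue rotation leaves greys unchanged and is invertible", {
  grey <- array(0.5, dim = c(4, 4, 3))
  expect_equal(pcai:::rotate_hue(grey, 0.2), grey, tolerance = 1e-2)
  # the YIQ-approximation matrix is only approximately orthogonal, so the
  # round trip is near- rather than exactly inverse
  spot <- toy_spot()
  back <- pcai:::rotate_hue(pcai:::rotate_hue(spot, 0.1), -0.1)
  expect_equal(back, spot, tolerance = 5e-3)
})

test_that("the dihedral group yields exactly 8 distinct variants", {
  patch <- array(stats::runif(5 * 5 * 3), dim = c(5, 5, 3))
  variants <- lapply(0:7, function(k) dihedral_variant(patch, k))
  keys <- vapply(variants, function(v) paste(signif(v, 12), collapse = ","),
                 character(1))
  expect_equal(length(unique(keys)), 8)
  expect_equal(variants[[1]], patch)  # k = 0 is the identity
  expect_error(dihedral_variant(patch, 8), "0..7")
})

test_that("four quarter rotations compose to the identity", {
  patch <- matrix(runif(16), 4, 4)
  out <- patch
  for (i in 1:4) out <- dihedral_variant(out, 1)
  expect_equal(out, patch)
  # mirror twice is also the identity
  expect_equal(dihedral_variant(dihedral_variant(patch, 4), 4), patch)
})

test_that("tissue fraction separates a tissue disc from white background", {
  spot <- toy_spot()
  frac <- tissue_fraction(spot)
  # disc of radius 0.45 * px covers ~pi * 0.45^2 of the square
  expect_equal(frac, pi * 0.45^2, tolerance = 0.05)
  white <- array(0.97, dim = c(16, 16, 3))
  expect_equal(tissue_fraction(white), 0)
})

test_that("area resampling preserves the overall mean", {
  mat <- matrix(runif(64 * 64), 64, 64)
  half <- pcai:::resample_area(mat, 0.5)
  expect_equal(dim(half), c(32, 32))
  expect_equal(mean(half), mean(mat), tolerance = 1e-12)
  const <- pcai:::resample_area(matrix(0.7, 30, 30), 0.37)
  expect_true(all(abs(const - 0.7) < 1e-12))
})

test_that("grid origins tile the resampled spot without overlap", {
  spec <- scale_spec(0.5, 16)
  g <- grid_origins(100, 100, spec, offset = c(3L, 5L))
  expect_equal(attr(g, "offset"), c(3L, 5L))
  # 100 px at scale 0.5 -> 50 px; 16-px tiles from offset 3 fit at 3 and 19
  expect_equal(sort(unique(g$row0)), c(3, 19))
  expect_equal(sort(unique(g$col0)), c(5, 21))
  expect_error(grid_origins(20, 20, spec), "too small")
})

test_that("random grid offsets always leave room for at least one tile", {
  spec <- scale_spec(1, 30)
  set.seed(12)
  for (i in 1:25) {
    g <- grid_origins(33, 64, spec)  # height barely above patch size
    expect_gte(nrow(g), 1)
    off <- attr(g, "offset")
    expect_lte(off[1], 33 - 30)
    expect_lte(off[2], 29)
  }
})

test_that("instance bags keep only tissue-bearing normalized patches", {
  spot <- toy_spot(px = 96, n_dark = 30)
  spec <- scale_spec(1, 24)
  bag <- make_instances(spot, spec, offset = c(0L, 0L))
  expect_s3_class(bag, "instance_bag")
  expect_equal(nrow(bag$origins), length(bag$patches))
  expect_lt(length(bag$patches), 16)  # corners are background-only
  # patches come from the standardized image: roughly centred values
  expect_lt(abs(mean(unlist(bag$patches))), 1.5)
  # a blank image yields no instances
  white <- array(0.97, dim = c(96, 96, 3))
  expect_error(make_instances(white, spec), "no instances")
})

test_that("the three-scale defaults mirror the 1.0 / 0.25 / 0.5 contexts", {
  sc <- default_scales()
  expect_equal(sc$s1$scale_factor, 1)
  expect_equal(sc$s025$scale_factor, 0.25)
  expect_equal(sc$s05$scale_factor, 0.5)
  expect_equal(sc$s05$patch_px, 352L)
  expect_error(scale_spec(0, 16), "scale_factor")
})
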