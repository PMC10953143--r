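test_that("min-max rescaling maps the range onto [0, 1]", {
  v <- volume3d(array(seq(10, 20, length.out = 27), dim = c(3, 3, 3)))
  r <- rescale_minmax(v)
  expect_equal(min(r$values), 0)
  expect_equal(max(r$values), 1)
  # a voxel at 15 maps to 0.5
  v2 <- volume3d(array(c(10, 15, 20, rep(10, 24)), dim = c(3, 3, 3)))
  expect_equal(rescale_minmax(v2)$values[2, 1, 1], 0.5)
  # idempotence on an already-normalized image
  r2 <- rescale_minmax(r)
  expect_lt(max(abs(r2$values - r$values)), 1e-12)
  expect_error(rescale_minmax(volume3d(array(0.3, c(3, 3, 3)))), "constant")
})

test_that("centred crop extracts the template-sized block", {
  big <- volume3d(array(0, dim = c(193, 229, 193)))
  cr <- crop_center(big, c(169, 208, 179))
  expect_equal(dim(cr$values), c(169L, 208L, 179L))
  # identity crop
  v <- rand_vol(c(6, 7, 8), seed = 2)
  expect_identical(crop_center(v, c(6, 7, 8))$values, v$values)
  # a spike at the grid centre stays at the centre of the crop
  sp <- array(0, dim = c(9, 9, 9)); sp[5, 5, 5] <- 1
  cc <- crop_center(volume3d(sp), c(5, 5, 5))
  expect_equal(which(cc$values == 1, arr.ind = TRUE)[1, ], c(3, 3, 3),
               ignore_attr = TRUE)
  expect_error(crop_center(v, c(10, 2, 2)), "exceeds")
})

test_that("trilinear resampling respects shape, constants and bounds", {
  v <- rand_vol(c(12, 14, 10), seed = 3)
  out <- resample_trilinear(v, c(8, 8, 8))
  expect_equal(dim(out$values), c(8L, 8L, 8L))
  expect_gte(min(out$values), min(v$values))
  expect_lte(max(out$values), max(v$values))
  # constants are preserved
  const <- resample_trilinear(volume3d(array(0.4, c(9, 9, 9))), c(5, 7, 6))
  expect_lt(max(abs(const$values - 0.4)), 1e-6)
  # linear ramps survive a down/up round trip (trilinear is exact on
  # affine functions under the corner-aligned convention)
  ramp <- volume3d(array(rep(seq(0, 1, length.out = 16), 16 * 16),
                         dim = c(16, 16, 16)))
  rt <- resample_trilinear(resample_trilinear(ramp, c(8, 8, 8)), c(16, 16, 16))
  expect_lt(max(abs(rt$values - ramp$values)), 1e-8)
})

test_that("the reference grid chain reproduces the published shapes", {
  # 193x229x193 template -> crop 169x208x179 -> resample 128^3
  big <- volume3d(array(runif(193 * 229 * 193), dim = c(193, 229, 193)))
  cropped <- crop_center(big, c(169, 208, 179))
  small <- resample_trilinear(cropped, c(128, 128, 128))
  expect_equal(dim(small$values), c(128L, 128L, 128L))
})

test_that("quality labels follow the max-grade rule on all 27 triplets", {
  for (cg in 0:2) for (mg in 0:2) for (ng in 0:2) {
    expected <- if (max(cg, mg, ng) == 2) "low"
    else if (max(cg, mg, ng) == 1) "medium" else "good"
    expect_identical(quality_label(quality_grades(cg, mg, ng)), expected)
  }
  expect_error(quality_label(c(0, 3, 0)), "grades")
})

test_that("dataset splitting is exhaustive, disjoint and deterministic", {
  mk <- function(label, i) list(label_t1ce = label, label_t1nce = "good",
                                id = i)
  pairs <- c(lapply(1:256, function(i) mk("medium", i)),
             lapply(257:300, function(i) mk("low", i)))
  sp <- split_dataset(pairs, test_fraction = 0.10, seed = 3)
  expect_length(sp$train, 230L)
  expect_length(sp$test_good, 26L)
  expect_length(sp$test_low, 44L)
  ids <- function(x) vapply(x, function(p) p$id, numeric(1))
  all_ids <- c(ids(sp$train), ids(sp$test_good), ids(sp$test_low))
  expect_setequal(all_ids, 1:300)
  expect_equal(anyDuplicated(all_ids), 0L)
  # determinism
  sp2 <- split_dataset(pairs, test_fraction = 0.10, seed = 3)
  expect_identical(ids(sp$train), ids(sp2$train))
  # all-low corner case
  low <- lapply(1:5, function(i) mk("low", i))
  sl <- split_dataset(low, 0.5, seed = 1)
  expect_length(sl$train, 0L)
  expect_length(sl$test_good, 0L)
  expect_length(sl$test_low, 5L)
  expect_error(split_dataset(pairs, 1.2, 1), "test_fraction")
})
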