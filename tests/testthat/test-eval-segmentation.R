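test_that("the intensity segmenter recovers the phantom tissues", {
  # noise-free phantom: classes are exactly separable
  s0 <- make_phantom(tiny_params(seed = 21, noise = 0))
  seg0 <- segment_tissues_simple(s0$t1nce, s0$brain_mask)
  expect_false(seg0$degenerate)
  bin0 <- binarize_maxprob(seg0)
  truth <- s0$tissue_truth$probabilities
  for (t in c("gm", "wm", "csf"))
    expect_identical(bin0[[t]][s0$brain_mask], truth[[t]][s0$brain_mask] > 0.5,
                     info = t)
  # noisy phantom: high (not perfect) agreement
  s <- make_phantom(tiny_params(seed = 22, noise = 0.02))
  seg <- segment_tissues_simple(s$t1nce, s$brain_mask)
  bin <- binarize_maxprob(seg)
  truth_lab <- ifelse(s$tissue_truth$probabilities$gm > .5, 1,
                      ifelse(s$tissue_truth$probabilities$wm > .5, 2, 3))
  est_lab <- ifelse(bin$gm, 1, ifelse(bin$wm, 2, 3))
  agree <- mean((est_lab == truth_lab)[s$brain_mask])
  expect_gt(agree, 0.95)
})

test_that("the segmenter is initialization-order invariant up to labels", {
  s <- make_phantom(tiny_params(seed = 23, noise = 0.02))
  a <- segment_tissues_simple(s$t1nce, s$brain_mask,
                              init_quantiles = c(0.15, 0.5, 0.85))
  b <- segment_tissues_simple(s$t1nce, s$brain_mask,
                              init_quantiles = c(0.85, 0.15, 0.5))
  for (t in c("gm", "wm", "csf"))
    expect_equal(a$probabilities[[t]], b$probabilities[[t]],
                 tolerance = 1e-8, info = t)
})

test_that("degenerate intensity distributions are flagged", {
  flat <- volume3d(array(rep(c(0.2, 0.8), 32), dim = c(4, 4, 4)))
  seg <- segment_tissues_simple(flat, array(TRUE, c(4, 4, 4)))
  expect_true(seg$degenerate)
  expect_error(binarize_maxprob(seg), "degenerate")
})

test_that("max-probability binarization follows the documented tie order", {
  d <- c(2, 2, 2)
  gm <- array(c(0.6, 0.4, 0.1, 0), dim = d)
  wm <- array(c(0.3, 0.4, 0.7, 0), dim = d)
  csf <- array(c(0.1, 0.2, 0.2, 0), dim = d)
  bin <- binarize_maxprob(tissue_maps(gm, wm, csf))
  expect_true(bin$gm[1])            # plain argmax
  expect_true(bin$gm[2])            # exact GM/WM tie -> GM
  expect_true(bin$wm[3])
  # disjoint masks whose union is the nonzero-probability support
  expect_equal(bin$gm + bin$wm + bin$csf, (gm + wm + csf > 0) + 0,
               ignore_attr = TRUE)
})

test_that("tissue volumes scale with the voxel edge cubed", {
  m <- array(FALSE, c(20, 20, 20)); m[1:1000] <- TRUE
  expect_equal(tissue_volume(m, 1), 1)
  expect_equal(tissue_volume(array(FALSE, c(4, 4, 4)), 2), 0)
  expect_equal(tissue_volume(m, 2), 8 * tissue_volume(m, 1))
  # anisotropic voxels use the product of edges
  expect_equal(tissue_volume(m, c(1, 2, 3)), 6)
})

test_that("AVD and VD satisfy their defining identities", {
  expect_equal(avd(500, 500, 1400, 1400), 0)
  expect_equal(avd(500, 480, 1400, 1400), 20)        # rescaling cancels
  expect_equal(vd(500, 480, 1400, 1450), 20 / 1400 * 1450, tolerance = 1e-12)
  expect_lt(vd(480, 500, 1400, 1400), 0)             # over-estimation by J
  set.seed(6)
  vi <- runif(1000, 100, 900); vj <- runif(1000, 100, 900)
  ti <- runif(1000, 1000, 2000); tb <- runif(1000, 1000, 2000)
  expect_equal(avd(vi, vj, ti, tb), abs(vd(vi, vj, ti, tb)))
  # linearity in the common rescaler
  expect_equal(avd(vi, vj, ti, 3 * tb), 3 * avd(vi, vj, ti, tb))
  expect_error(vd(1, 2, 0, 1), "tiv_i")
})

test_that("Dice overlap matches set arithmetic", {
  d <- c(4, 4, 4)
  a <- array(FALSE, d); a[1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, d); b[11:20] <- TRUE
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 20 with overlap 10
  a2 <- array(FALSE, d); a2[1:20] <- TRUE
  b2 <- array(FALSE, d); b2[11:30] <- TRUE
  expect_equal(dice(a2, b2), 0.5)
  expect_true(is.na(dice(array(FALSE, d), array(FALSE, d))))
  expect_error(dice(a, array(FALSE, c(3, 4, 4))), "grid")
})

test_that("resampling back restores the reference grid", {
  v <- rand_vol(c(12, 12, 12), seed = 9)
  out <- resample_back(v, c(9, 10, 11))
  expect_equal(dim(out$values), c(9L, 10L, 11L))
  const <- resample_back(resample_back(volume3d(array(0.4, c(8, 8, 8))),
                                       c(6, 6, 6)), c(8, 8, 8))
  expect_lt(max(abs(const$values - 0.4)), 1e-9)
})

test_that("segmentation comparison reports consistent AVD/VD/Dice", {
  s <- make_phantom(tiny_params(seed = 31, noise = 0.02))
  msk <- s$brain_mask
  ref <- segment_tissues_simple(s$t1nce, msk)
  cmp <- segment_tissues_simple(s$t1ce, msk)
  tab <- compare_segmentations(ref, cmp, tiv_bar = 1400)
  expect_equal(tab$avd, abs(tab$vd))
  expect_true(all(tab$dice >= 0 & tab$dice <= 1))
  expect_equal(tab$tissue, c("gm", "wm", "csf"))
  # TIV additivity: the reference TIV equals the summed tissue volumes
  tv <- tissue_volumes(binarize_maxprob(ref), ref$voxel_size_mm)
  expect_equal(unname(tab$tiv_ref[1]), sum(tv$volumes), tolerance = 1e-9)
})
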