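test_that("phantom generation is deterministic and seed-sensitive", {
  p <- tiny_params(seed = 7)
  a <- make_phantom(p)
  b <- make_phantom(p)
  expect_identical(a$t1nce$values, b$t1nce$values)
  expect_identical(a$t1ce$values, b$t1ce$values)
  expect_identical(a$brain_mask, b$brain_mask)
  expect_identical(a$tissue_truth$probabilities, b$tissue_truth$probabilities)

  c <- make_phantom(tiny_params(seed = 8))
  expect_true(any(a$t1nce$values != c$t1nce$values))
})

test_that("noise-free phantom hits the tissue means exactly", {
  s <- make_phantom(tiny_params(seed = 7, noise = 0))
  pr <- s$tissue_truth$probabilities
  expect_true(all(s$t1nce$values[pr$wm > 0.5] == 0.75))
  expect_true(all(s$t1nce$values[pr$gm > 0.5] == 0.55))
  expect_true(all(s$t1nce$values[pr$csf > 0.5] == 0.20))
})

test_that("tissue probabilities sum to one inside the brain mask", {
  s <- make_phantom(tiny_params(seed = 3))
  pr <- s$tissue_truth$probabilities
  tot <- pr$gm + pr$wm + pr$csf
  expect_true(all(abs(tot[s$brain_mask] - 1) < 1e-6))
  # the brain mask covers every voxel with nonzero tissue probability
  expect_true(all(s$brain_mask[tot > 0]))
})

test_that("enhancement is additive, local and clipped", {
  s <- make_phantom(tiny_params(seed = 5, noise = 0))
  # identity case
  same <- apply_enhancement(s, delta = 0, contrast_shift = 0)
  expect_identical(same$values, s$t1nce$values)
  # additive uplift inside the enhancing compartment (no clipping at 0.1)
  enh <- apply_enhancement(s, delta = 0.1, contrast_shift = 0)
  d <- enh$values - s$t1nce$values
  expect_equal(mean(d[s$enhancing]), 0.1, tolerance = 1e-12)
  # locality: untouched outside enhancing and GM compartments
  gm <- s$tissue_truth$probabilities$gm > 0.5
  outside <- !s$enhancing & !gm
  expect_true(all(d[outside] == 0))
  # clipping keeps the intensity contract
  big <- apply_enhancement(s, delta = 0.9, contrast_shift = 0.3)
  expect_true(max(big$values) <= 1 && min(big$values) >= 0)
})

test_that("masked error between the pair grows monotonically with delta", {
  s <- make_phantom(tiny_params(seed = 11))
  deltas <- c(0, 0.05, 0.1, 0.2, 0.3)
  maes <- vapply(deltas, function(d)
    mae(apply_enhancement(s, delta = d, contrast_shift = 0), s$t1nce,
        s$brain_mask), numeric(1))
  expect_true(all(diff(maes) >= 0))
})

test_that("quality degradation honours grades and determinism", {
  s <- make_phantom(tiny_params(seed = 2))
  v <- s$t1nce
  # grade (0,0,0) is bit-identical
  expect_identical(degrade_quality(v, quality_grades(0, 0, 0), 1)$values,
                   v$values)
  # severe contrast compresses more than medium contrast
  g1 <- degrade_quality(v, quality_grades(1, 0, 0), seed = 4)
  g2 <- degrade_quality(v, quality_grades(2, 0, 0), seed = 4)
  m <- s$brain_mask
  expect_lt(sd(g2$values[m]), sd(g1$values[m]))
  # reproducible noise injection
  n1 <- degrade_quality(v, quality_grades(0, 0, 2), seed = 9)
  n2 <- degrade_quality(v, quality_grades(0, 0, 2), seed = 9)
  expect_identical(n1$values, n2$values)
  expect_true(any(n1$values != v$values))
  # motion blur smooths along one axis
  b1 <- degrade_quality(v, quality_grades(0, 2, 0), seed = 9)
  expect_lt(sd(b1$values[m]), sd(v$values[m]))
})

test_that("grade and parameter validation errors are explicit", {
  expect_error(quality_grades(3, 0, 0), "grades")
  expect_error(phantom_params(grid_shape = c(4, 16, 16)), ">= 8")
  expect_error(phantom_params(delta = -1), "delta")
  expect_error(phantom_params(tissue_means = c(wm = 1.5, gm = .5, csf = .2,
                                               background = 0)), "\\[0, 1\\]")
})

test_that("simulated datasets write a complete BIDS-like tree", {
  dir <- file.path(tempdir(), "bids_small")
  unlink(dir, recursive = TRUE)
  man <- simulate_dataset(dir, n_pairs = 3L, params = tiny_params(),
                          n_low_t1ce = 1L, seed = 5)
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(man$path_t1ce)))
  expect_true(all(file.exists(man$path_t1nce)))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  # exactly one low-quality T1ce, and no low-quality T1nce
  expect_equal(sum(man$label_t1ce == "low"), 1L)
  expect_false(any(man$label_t1nce == "low"))
  # sidecars carry grades
  js <- jsonlite::fromJSON(sub("\\.nii\\.gz$", ".json", man$path_t1ce[1]))
  expect_true(all(c("QualityGrades", "QualityLabel", "GroundTruth") %in%
                    names(js)))
})
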