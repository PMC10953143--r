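test_that("mask union is a voxelwise OR with shape checking", {
  a <- array(FALSE, c(5, 5, 5)); a[1:10] <- TRUE
  b <- array(FALSE, c(5, 5, 5)); b[101:120] <- TRUE
  u <- mask_union(a, b)
  expect_equal(sum(u), 30L)
  expect_identical(mask_union(a, a), a)
  expect_identical(mask_union(a, array(FALSE, c(5, 5, 5))), a)
  expect_error(mask_union(a, array(FALSE, c(4, 5, 5))), "differ")
})

test_that("MAE is a symmetric percentage with a zero self-limit", {
  x <- rand_vol(c(8, 8, 8), seed = 1, lo = 0, hi = 0.9)
  m <- array(TRUE, c(8, 8, 8))
  expect_equal(mae(x, x, m), 0)
  y <- volume3d(x$values + 0.05)
  expect_equal(mae(x, y, m), 5, tolerance = 1e-12)
  z <- rand_vol(c(8, 8, 8), seed = 2)
  expect_equal(mae(x, z, m), mae(z, x, m))
  expect_error(mae(x, y, array(FALSE, c(8, 8, 8))), "empty")
})

test_that("PSNR follows its closed form and infinite self-limit", {
  x <- rand_vol(c(8, 8, 8), seed = 3, lo = 0, hi = 0.8)
  m <- array(TRUE, c(8, 8, 8))
  expect_identical(psnr(x, x, m), Inf)
  y <- volume3d(x$values + 0.1)   # MSE = 0.01
  expect_equal(psnr(x, y, m), 20, tolerance = 1e-12)
  # doubling the data range raises PSNR by 20*log10(2)
  expect_equal(psnr(x, y, m, data_range = 2) - psnr(x, y, m),
               20 * log10(2), tolerance = 1e-12)
})

test_that("SSIM matches a brute-force per-window oracle", {
  set.seed(4)
  d <- c(8, 8, 8)
  x <- array(runif(prod(d)), d)
  y <- 0.7 * x + 0.3 * array(runif(prod(d)), d)
  msk <- array(runif(prod(d)) > 0.3, d)
  w <- 3L; h <- 1L
  C1 <- 0.01^2; C2 <- 0.03^2
  # brute force: loop over all fully-contained windows, mask the
  # intensities, average the map over in-mask centres
  xm <- x * msk; ym <- y * msk
  vals <- c(); cen <- c()
  for (i in (1 + h):(d[1] - h)) for (j in (1 + h):(d[2] - h))
    for (k in (1 + h):(d[3] - h)) {
      wx <- xm[(i - h):(i + h), (j - h):(j + h), (k - h):(k + h)]
      wy <- ym[(i - h):(i + h), (j - h):(j + h), (k - h):(k + h)]
      mx <- mean(wx); my <- mean(wy)
      vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
      cxy <- mean(wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
      cen <- c(cen, msk[i, j, k])
    }
  oracle <- mean(vals[cen])
  expect_equal(ssim(x, y, msk, window = 3), oracle, tolerance = 1e-6)
  # self-similarity is exactly 1; an inverted image scores below 1
  expect_equal(ssim(x, x, msk, window = 3), 1, tolerance = 1e-12)
  expect_lt(ssim(x, 1 - x, msk, window = 3), 1)
  expect_error(ssim(x, y, msk, window = 9), "larger")
})

test_that("metrics never see intensities outside the mask", {
  set.seed(5)
  d <- c(10, 10, 10)
  x <- array(runif(prod(d)), d)
  y <- array(runif(prod(d)), d)
  msk <- array(FALSE, d); msk[3:8, 3:8, 3:8] <- TRUE
  x2 <- x; y2 <- y
  x2[!msk] <- 0.99; y2[!msk] <- runif(sum(!msk))
  expect_identical(mae(x, y, msk), mae(x2, y2, msk))
  expect_identical(psnr(x, y, msk), psnr(x2, y2, msk))
  expect_equal(ssim(x, y, msk), ssim(x2, y2, msk), tolerance = 1e-12)
})

test_that("paired t-tests match the closed form and Bonferroni capping", {
  # identical samples: t = 0, corrected p = 1
  r0 <- paired_ttest_bonferroni(list(null = list(x = 1:5, y = 1:5)))
  expect_equal(r0$t, 0)
  expect_equal(r0$p_corrected, 1)
  # closed-form check for d = (1, 2, 3, 4)
  x <- c(2, 4, 6, 8); y <- c(1, 2, 3, 4)   # d = 1:4
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  r1 <- paired_ttest_bonferroni(list(a = list(x = x, y = y)), m = 1)
  expect_equal(r1$t, t_hand, tolerance = 1e-12)
  expect_equal(r1$p, p_hand, tolerance = 1e-12)
  # m = 10 multiplies the raw p, capped at 1
  r10 <- paired_ttest_bonferroni(list(a = list(x = x, y = y)), m = 10)
  expect_equal(r10$p_corrected, min(1, 10 * p_hand))
  # constant nonzero differences are degenerate, not a number
  rz <- paired_ttest_bonferroni(list(a = list(x = c(2, 3, 4), y = c(1, 2, 3))))
  expect_true(rz$degenerate)
  expect_true(is.na(rz$t))
})
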