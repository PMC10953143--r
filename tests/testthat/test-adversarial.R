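test_that("the reference patch lattice yields eight 64^3 patches at stride 50", {
  vol <- array(0, dim = c(128, 128, 128))
  ps <- extract_patches(vol, patch_size = 64, stride = 50)
  expect_length(ps$patches, 8L)
  expect_setequal(unique(ps$origins[, 1]), c(0L, 50L))
  expect_setequal(unique(ps$origins[, 2]), c(0L, 50L))
  expect_setequal(unique(ps$origins[, 3]), c(0L, 50L))
  expect_true(all(vapply(ps$patches, function(p)
    identical(dim(p), c(64L, 64L, 64L)), logical(1))))
})

test_that("patch origins follow the lattice rule and lexicographic order", {
  # whole-volume patch
  one <- extract_patches(array(0, c(64, 64, 64)), 64, 50)
  expect_length(one$patches, 1L)
  expect_equal(unname(one$origins[1, ]), c(0L, 0L, 0L))
  # stride = patch size tiles the volume exactly
  v <- rand_vol(c(16, 16, 16), seed = 4)$values
  tiled <- extract_patches(v, 8, 8)
  expect_length(tiled$patches, 8L)
  re <- reassemble_patches(tiled)
  expect_true(all(re$covered))
  expect_identical(re$values, v)
  # lexicographic enumeration of origins
  ord <- do.call(order, as.data.frame(tiled$origins))
  expect_identical(ord, seq_len(nrow(tiled$origins)))
  # trailing sliver beyond the last admissible origin is dropped
  sliver <- extract_patches(array(0, c(20, 16, 16)), 8, 8)
  expect_setequal(unique(sliver$origins[, 1]), c(0L, 8L))
  expect_error(extract_patches(array(0, c(4, 4, 4)), 8, 2), "exceeds")
})

test_that("discriminator scores are bounded, deterministic and aggregable", {
  dcfg <- discriminator_config(patch_size = 8, base_channels = 4, seed = 2)
  disc <- build_discriminator(dcfg)
  set.seed(9)
  v <- array(runif(16^3) * 2 - 1, c(16, 16, 16))
  w <- array(runif(16^3) * 2 - 1, c(16, 16, 16))
  cond <- extract_patches(v, 8, 8)
  cand <- extract_patches(w, 8, 8)
  scores <- vapply(seq_along(cond$patches), function(j)
    disc$forward(cond$patches[[j]], cand$patches[[j]])$value, numeric(1))
  expect_length(scores, 8L)
  expect_true(all(scores > 0 & scores < 1))
  expect_true(all(is.finite(scores)))
  # volume-level score is the mean of per-patch scores
  expect_equal(mean(scores), sum(scores) / 8)
  # determinism
  s2 <- disc$forward(cond$patches[[1]], cand$patches[[1]])$value
  expect_identical(scores[1], s2)
  expect_error(disc$forward(cond$patches[[1]],
                            array(0, c(4, 4, 4, 1))), "mismatch")
  expect_error(discriminator_config(patch_size = 12), "divisible")
})

test_that("soft labels fall in their configured ranges with the right mean", {
  conv <- soft_label_config("conventional")
  lit <- soft_label_config("paper_literal")
  set.seed(11)
  r <- draw_soft_label("real", conv, 1e4)
  f <- draw_soft_label("fake", conv, 1e4)
  expect_true(all(r >= 0.7 & r <= 1))
  expect_true(all(f >= 0 & f <= 0.3))
  # literal mode swaps the ranges
  rl <- draw_soft_label("real", lit, 100)
  expect_true(all(rl >= 0 & rl <= 0.3))
  # Monte-Carlo mean within 3 sd of the range midpoint
  se <- 0.3 / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(r) - 0.85), 3 * se)
  expect_lt(abs(mean(f) - 0.15), 3 * se)
})

test_that("generator loss decomposes into adversarial and L1 terms", {
  cfg_ls <- train_config(loss_mode = "least_squares")
  cfg_ce <- train_config(loss_mode = "cross_entropy")
  real <- rand_vol(c(6, 6, 6), seed = 1, lo = 0, hi = 0.8)
  # perfect generator at the label operating point
  rec <- generator_loss(p_fake = c(1, 1), fake = real, real = real,
                        cfg = cfg_ls, labels = list(real = 1, fake = 0))
  expect_equal(rec$L_G, 0)
  expect_equal(rec$L1_term, 0)
  # constant offset of 0.1 with a zero adversarial term
  fake <- volume3d(real$values + 0.1)
  rec2 <- generator_loss(p_fake = 1, fake = fake, real = real, cfg = cfg_ls)
  expect_equal(rec2$L_G, 0.1, tolerance = 1e-12)
  expect_equal(rec2$adversarial_term, 0)
  # literal log form is zero at its optimum
  rec3 <- generator_loss(p_fake = 1, fake = real, real = real, cfg = cfg_ce)
  expect_equal(rec3$L_G, 0)
  # epsilon guard keeps the log finite at p = 0
  rec4 <- generator_loss(p_fake = 0, fake = real, real = real, cfg = cfg_ce)
  expect_true(is.finite(rec4$L_G))
})

test_that("discriminator loss reaches zero at its operating points", {
  cfg_ls <- train_config(loss_mode = "least_squares")
  cfg_ce <- train_config(loss_mode = "cross_entropy")
  # literal log form: perfect discriminator
  expect_equal(discriminator_loss(1, 0, cfg_ce), 0)
  # least squares at hard labels with undecided scores
  expect_equal(discriminator_loss(0.5, 0.5, cfg_ls,
                                  labels = list(real = 1, fake = 0)), 0.25)
  # zero exactly at the (soft) labels
  expect_equal(discriminator_loss(0.83, 0.12, cfg_ls,
                                  labels = list(real = 0.83, fake = 0.12)), 0)
  expect_true(is.finite(discriminator_loss(0, 1, cfg_ce)))
})

test_that("generator-only training is seeded, monotone-checkpointed and learns", {
  pairs <- tiny_pairs(6, grid = 16)
  cfg <- generator_config("att", input_shape = c(16, 16, 16), depth = 2L,
                          base_channels = 4L, seed = 4)
  tc <- train_config(epochs = 4, seed = 9, lr = 2e-3)
  run <- train_generator_only(pairs, cfg, tc)
  expect_equal(nrow(run$history), 4L)
  # best checkpoint loss is <= every epoch loss
  expect_true(all(run$checkpoint$meta$loss <= run$history$loss + 1e-12))
  # learning sanity: loss decreases on this separable synthetic task
  expect_lt(run$history$loss[4], run$history$loss[1])
  # bit-level determinism of the trajectory
  run2 <- train_generator_only(pairs, cfg, tc)
  expect_identical(run$history$loss, run2$history$loss)
})

test_that("discriminator pretraining separates real from generated patches", {
  pairs <- tiny_pairs(3, grid = 16)
  gcfg <- generator_config("res", input_shape = c(16, 16, 16), depth = 2L,
                           base_channels = 4L, seed = 8)
  gen <- build_generator(gcfg)
  dcfg <- discriminator_config(patch_size = 8, base_channels = 4, seed = 3)
  # zero epochs: initialized weights unchanged
  init <- pretrain_discriminator(pairs, gen, dcfg, train_config(epochs = 0))
  fresh <- build_discriminator(dcfg)
  expect_identical(init$checkpoint$values,
                   lapply(fresh$params, function(p) p$value))
  pre <- pretrain_discriminator(pairs, gen, dcfg,
                                train_config(epochs = 3, seed = 5, lr = 2e-3))
  disc <- restore_model(pre$checkpoint)
  to_net3 <- decontrast:::to_net3
  seps <- unlist(lapply(pairs, function(p) {
    x <- to_net3(p$t1ce$values)
    t <- to_net3(p$t1nce$values)
    f <- to_net3(translate_volume(gen, p$t1ce)$values)
    cond <- extract_patches(x, 8, 8)
    real <- extract_patches(t, 8, 8)
    fake <- extract_patches(f, 8, 8)
    vapply(1:8, function(j)
      disc$forward(cond$patches[[j]], real$patches[[j]])$value -
        disc$forward(cond$patches[[j]], fake$patches[[j]])$value, numeric(1))
  }))
  expect_gt(mean(seps), 0)  # mean p_real > mean p_fake on held-in patches
})

test_that("warm-started adversarial training stays finite and seeded", {
  pairs <- tiny_pairs(2, grid = 16)
  gcfg <- generator_config("res", input_shape = c(16, 16, 16), depth = 2L,
                           base_channels = 4L, seed = 8)
  g <- train_generator_only(pairs, gcfg, train_config(epochs = 2, seed = 1,
                                                      lr = 1e-3))
  dcfg <- discriminator_config(patch_size = 8, base_channels = 4, seed = 3)
  d <- pretrain_discriminator(pairs, g$checkpoint, dcfg,
                              train_config(epochs = 1, seed = 2, lr = 1e-3))
  tc <- train_config(epochs = 2, seed = 7, lr = 1e-4)
  cg <- suppressWarnings(train_cgan(pairs, g$checkpoint, d$checkpoint, tc))
  expect_equal(nrow(cg$history), 2L)
  expect_true(all(is.finite(unlist(cg$history[, -1]))))
  expect_true(all(cg$history$L1_term >= 0))
  # seeded determinism of the adversarial trajectory
  cg2 <- suppressWarnings(train_cgan(pairs, g$checkpoint, d$checkpoint, tc))
  expect_identical(cg$history, cg2$history)
  # a huge L1 weight reduces training to generator-only behaviour
  tc_l1 <- train_config(epochs = 1, seed = 7, lr = 1e-4, l1_weight = 1e6)
  cg3 <- suppressWarnings(train_cgan(pairs, g$checkpoint, d$checkpoint, tc_l1))
  expect_lt(cg3$history$adversarial_term[1] / cg3$history$L_G[1], 1e-3)
})
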