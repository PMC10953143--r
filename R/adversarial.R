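#' Extract a regular lattice of cubic patches
#'
#' Per axis, the patch origins are `{0, stride, 2*stride, ...}` intersected
#' with `{o : o + patch_size <= axis length}`; patches are enumerated in
#' lexicographic origin order.  On a 128^3 volume with 64^3 patches and
#' stride 50 this yields the eight patches at per-axis origins `{0, 50}`.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param patch_size cubic patch edge (voxels).
#' @param stride origin spacing (voxels).
#' @return A `patch_set`: list with `patches` (list of 3D arrays),
#'   `origins` (n x 3 matrix, 0-based), `patch_size`, `stride`,
#'   `parent_shape`.
#' @export
extract_patches <- function(vol, patch_size, stride) {
  x <- vol_values(vol)
  d <- dim(x)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  stopifnot(patch_size >= 1L, stride >= 1L)
  if (any(patch_size > d))
    stop("patch_size ", patch_size, " exceeds volume shape ",
         paste(d, collapse = "x"))
  ax <- lapply(d, function(n) seq(0L, n - patch_size, by = stride))
  origins <- as.matrix(expand.grid(o3 = ax[[3L]], o2 = ax[[2L]],
                                   o1 = ax[[1L]]))[, 3:1, drop = FALSE]
  colnames(origins) <- c("o1", "o2", "o3")
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    o <- origins[i, ]
    x[(o[1L] + 1L):(o[1L] + patch_size),
      (o[2L] + 1L):(o[2L] + patch_size),
      (o[3L] + 1L):(o[3L] + patch_size), drop = FALSE]
  })
  structure(list(patches = patches, origins = origins,
                 patch_size = patch_size, stride = stride,
                 parent_shape = d),
            class = "patch_set")
}

#' Reassemble patches onto the parent grid
#'
#' Places every patch back at its origin.  Overlapping regions are written
#' identically (patches are crops of one parent), so the covered region
#' reproduces the parent exactly.
#'
#' @param pset a `patch_set` from [extract_patches()].
#' @return A list with `values` (parent-shaped array, zero where uncovered)
#'   and `covered` (logical array).
#' @export
reassemble_patches <- function(pset) {
  stopifnot(inherits(pset, "patch_set"))
  out <- array(0, dim = pset$parent_shape)
  cov <- array(FALSE, dim = pset$parent_shape)
  ps <- pset$patch_size
  for (i in seq_along(pset$patches)) {
    o <- pset$origins[i, ]
    i1 <- (o[1L] + 1L):(o[1L] + ps)
    i2 <- (o[2L] + 1L):(o[2L] + ps)
    i3 <- (o[3L] + 1L):(o[3L] + ps)
    out[i1, i2, i3] <- pset$patches[[i]]
    cov[i1, i2, i3] <- TRUE
  }
  list(values = out, covered = cov)
}

#' Patch discriminator configuration
#'
#' The conditional discriminator scores a (conditioning T1ce patch,
#' candidate T1nce patch) pair: the two patches are channel-concatenated
#' and passed through four blocks — three 3D convolutions with
#' LeakyReLU(alpha) and stride-2 downsampling, then a 3D convolution
#' followed by global average pooling — and a sigmoid squashing, giving one
#' score in (0, 1) interpretable as the probability that the candidate is
#' real.
#'
#' @param patch_size cubic patch edge; must be divisible by 8.
#' @param base_channels channels of the first block.
#' @param alpha LeakyReLU negative slope.
#' @param seed integer seed for weight initialization.
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(patch_size = 16L, base_channels = 8L,
                                 alpha = 0.2, seed = 1L) {
  patch_size <- as.integer(patch_size)
  if (patch_size %% 8L != 0L)
    stop("`patch_size` must be divisible by 8 (three stride-2 blocks)")
  structure(list(patch_size = patch_size,
                 base_channels = as.integer(base_channels),
                 alpha = alpha, seed = as.integer(seed)),
            class = "discriminator_config")
}

#' Build the patch discriminator
#'
#' @param cfg a [discriminator_config()].
#' @return A `patch_discriminator`: list with `cfg`, `params` and
#'   `forward(cond, cand)` mapping two `c(p, p, p, 1)` patches (arrays or
#'   nodes, network intensity convention) to a scalar score node in (0, 1).
#' @export
build_discriminator <- function(cfg) {
  stopifnot(inherits(cfg, "discriminator_config"))
  c1 <- cfg$base_channels
  st <- new_param_store()
  with_seed(cfg$seed, {
    st_conv(st, "b1", 4L, 2L, c1)
    st_conv(st, "b2", 4L, c1, 2L * c1)
    st_conv(st, "b3", 4L, 2L * c1, 4L * c1)
    st_conv(st, "b4", 3L, 4L * c1, 1L)
  })
  P <- st$params
  a <- cfg$alpha
  ps <- cfg$patch_size

  forward <- function(cond, cand) {
    cond <- as_input_node(cond)
    cand <- as_input_node(cand)
    if (!identical(dim(cond$value), dim(cand$value)))
      stop("patch shape mismatch between conditioning and candidate")
    if (!all(dim(cond$value)[1:3] == ps))
      stop("patches must be ", ps, "^3 for this discriminator")
    h <- ad_concat(cond, cand)
    h <- ad_leaky_relu(fwd_conv(P, "b1", h, 2L, 1L), a)
    h <- ad_leaky_relu(fwd_conv(P, "b2", h, 2L, 1L), a)
    h <- ad_leaky_relu(fwd_conv(P, "b3", h, 2L, 1L), a)
    h <- fwd_conv(P, "b4", h, 1L, 1L)
    ad_sigmoid(ad_mean(h))   # global average pooling + squash to (0, 1)
  }
  structure(list(cfg = cfg, params = P, forward = forward),
            class = "patch_discriminator")
}

#' @export
print.patch_discriminator <- function(x, ...) {
  cat(sprintf("<patch_discriminator> patch=%d^3 base=%d params=%d\n",
              x$cfg$patch_size, x$cfg$base_channels, n_params(x)))
  invisible(x)
}

#' Soft adversarial labels
#'
#' Soft labels replace the hard 0/1 adversarial targets by uniform draws
#' from narrow sub-intervals to stabilize discriminator training.  In
#' `conventional` mode real targets lie in `[0.7, 1]` and fake targets in
#' `[0, 0.3]`; `paper_literal` mode swaps the two ranges (reproducing the
#' published description, whose direction contradicts the discriminator
#' loss optimum and is therefore not the default).
#'
#' @param mode `"conventional"` or `"paper_literal"`.
#' @return An object of class `soft_label_config`.
#' @export
soft_label_config <- function(mode = c("conventional", "paper_literal")) {
  mode <- match.arg(mode)
  r <- if (mode == "conventional") list(real = c(0.7, 1), fake = c(0, 0.3))
  else list(real = c(0, 0.3), fake = c(0.7, 1))
  structure(c(r, list(mode = mode)), class = "soft_label_config")
}

#' @param kind `"real"` or `"fake"`.
#' @param cfg a [soft_label_config()].
#' @param n number of draws.
#' @return `draw_soft_label()`: `n` uniform draws from the configured range.
#' @rdname soft_label_config
#' @export
draw_soft_label <- function(kind = c("real", "fake"),
                            cfg = soft_label_config(), n = 1L) {
  kind <- match.arg(kind)
  rng <- cfg[[kind]]
  stats::runif(n, rng[1L], rng[2L])
}

#' Training configuration
#'
#' Optimization settings shared by the generator-only and conditional-GAN
#' training loops.  Reference-scale defaults follow the published protocol
#' (Adam, L1 loss, batch size 2 for generator-only training, batch size 1
#' for the cGAN, 300 epochs, best-training-loss checkpointing); learning
#' rate and betas follow the conditional-GAN literature.
#'
#' @param epochs number of epochs (>= 0; 0 returns initialized weights).
#' @param batch_size_generator_only,batch_size_cgan batch sizes.
#' @param l1_weight weight lambda of the L1 term in the generator loss.
#' @param loss_mode `"least_squares"` (default) or `"cross_entropy"` (the
#'   literal log-loss form of the published equations).
#' @param lr,beta1,beta2 Adam settings.
#' @param seed integer seed controlling shuffling, soft labels and
#'   initialization-independent randomness of the loops.
#' @param soft_labels a [soft_label_config()].
#' @param eps epsilon floor inside logarithms.
#' @param patch_size,patch_stride discriminator patch lattice; `NULL`
#'   scales the reference 64/50-on-128 lattice to the volume size.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 300L,
                         batch_size_generator_only = 2L,
                         batch_size_cgan = 1L,
                         l1_weight = 1,
                         loss_mode = c("least_squares", "cross_entropy"),
                         lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         seed = 1L,
                         soft_labels = soft_label_config(),
                         eps = 1e-7,
                         patch_size = NULL, patch_stride = NULL) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(epochs >= 0L, l1_weight >= 0, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size_generator_only = as.integer(batch_size_generator_only),
                 batch_size_cgan = as.integer(batch_size_cgan),
                 l1_weight = l1_weight, loss_mode = loss_mode,
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), soft_labels = soft_labels,
                 eps = eps, patch_size = patch_size,
                 patch_stride = patch_stride),
            class = "train_config")
}

default_patch_lattice <- function(d, cfg) {
  ps <- cfg$patch_size %||% as.integer(d[1L] %/% 2L)
  st <- cfg$patch_stride %||% max(1L, as.integer(round(d[1L] * 50 / 128)))
  list(patch_size = as.integer(ps), stride = as.integer(st))
}

loss_record <- function(L_G = NA_real_, L_D = NA_real_, L1_term = NA_real_,
                        adversarial_term = NA_real_, epoch = NA_integer_) {
  structure(list(L_G = L_G, L_D = L_D, L1_term = L1_term,
                 adversarial_term = adversarial_term, epoch = epoch),
            class = "loss_record")
}

#' Generator loss
#'
#' `L_G = adversarial_term + lambda * L1_term` with
#' `L1_term = mean |real - fake|`.  In `least_squares` mode the adversarial
#' term is `mean((p_fake - real_label)^2)`; in `cross_entropy` mode it is
#' the literal log form `-mean(log p_fake)` (epsilon-guarded).
#'
#' @param p_fake discriminator scores of the generated patches (vector).
#' @param fake,real generated and true volumes ([volume3d()] or arrays, one
#'   intensity convention).
#' @param cfg a [train_config()].
#' @param labels list with elements `real`, `fake` (targets; default hard
#'   labels 1/0).
#' @return A `loss_record` with `L_G`, `L1_term`, `adversarial_term`.
#' @export
generator_loss <- function(p_fake, fake, real, cfg = train_config(),
                           labels = list(real = 1, fake = 0)) {
  fv <- vol_values(fake); rv <- vol_values(real)
  stopifnot(identical(dim(fv), dim(rv)))
  l1 <- mean(abs(rv - fv))
  adv <- switch(cfg$loss_mode,
                least_squares = mean((p_fake - labels$real)^2),
                cross_entropy = -mean(log(pmax(p_fake, cfg$eps))))
  loss_record(L_G = adv + cfg$l1_weight * l1, L1_term = l1,
              adversarial_term = adv)
}

#' Discriminator loss
#'
#' In `least_squares` mode,
#' `0.5 * mean((p_real - real_label)^2) + 0.5 * mean((p_fake - fake_label)^2)`;
#' in `cross_entropy` mode the literal log form
#' `-0.5 * mean(log p_real) - 0.5 * mean(log(1 - p_fake))`.
#'
#' @param p_real,p_fake discriminator scores for true and generated patches
#'   (equal-length vectors).
#' @inheritParams generator_loss
#' @return Scalar loss value.
#' @export
discriminator_loss <- function(p_real, p_fake, cfg = train_config(),
                               labels = list(real = 1, fake = 0)) {
  stopifnot(length(p_real) == length(p_fake))
  switch(cfg$loss_mode,
         least_squares =
           0.5 * mean((p_real - labels$real)^2) +
           0.5 * mean((p_fake - labels$fake)^2),
         cross_entropy =
           -0.5 * mean(log(pmax(p_real, cfg$eps))) -
           0.5 * mean(log(pmax(1 - p_fake, cfg$eps))))
}

## ---- training loops ---------------------------------------------------------

check_finite_loss <- function(x, what) {
  if (!all(is.finite(x)))
    stop("training diverged: non-finite ", what, " loss")
  x
}

scale_grads <- function(params, k) {
  if (k == 1) return(invisible())
  for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / k
  invisible()
}

#' Train a generator with the L1 objective only
#'
#' Plain supervised training of one generator on paired volumes: Adam on
#' `mean |G(T1ce) - T1nce|` in the network's `[-1, 1]` intensity
#' convention.  The parameters of the epoch with the best (lowest) mean
#' training loss are kept as the checkpoint.  Fully seeded: identical data,
#' configuration and seed reproduce the loss trajectory.
#'
#' @param pairs list of image pairs, each with `t1ce` and `t1nce`
#'   [volume3d()] members in `[0, 1]`.
#' @param gen_cfg a [generator_config()].
#' @param train_cfg a [train_config()].
#' @return A list with `checkpoint` (best epoch), `model` (final state) and
#'   `history` (data.frame epoch/loss).
#' @export
train_generator_only <- function(pairs, gen_cfg, train_cfg = train_config()) {
  stopifnot(length(pairs) >= 1L)
  model <- build_generator(gen_cfg)
  n <- length(pairs)
  xs <- lapply(pairs, function(p) to_net(vol_values(p$t1ce)))
  ts <- lapply(pairs, function(p) to_net(vol_values(p$t1nce)))
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  best <- list(loss = Inf, ckpt = checkpoint(model, epoch = 0L, loss = NA_real_))
  bs <- max(1L, train_cfg$batch_size_generator_only)

  with_seed(train_cfg$seed, {
    for (e in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = bs)) {
        batch <- ord[start:min(start + bs - 1L, n)]
        for (i in batch) {
          y <- model$forward(ad_const(xs[[i]]), train = TRUE)
          loss <- ad_mean_abs(y, ad_const(ts[[i]]))
          ad_backward(loss)
          losses <- c(losses, loss$value)
        }
        scale_grads(model$params, length(batch))
        state <- adam_step(model$params, state, lr = train_cfg$lr,
                           beta1 = train_cfg$beta1, beta2 = train_cfg$beta2)
      }
      el <- mean(check_finite_loss(losses, "L1"))
      history <- rbind(history, data.frame(epoch = e, loss = el))
      if (el < best$loss)
        best <- list(loss = el, ckpt = checkpoint(model, epoch = e, loss = el))
    }
  })
  list(checkpoint = best$ckpt, model = model, history = history)
}

#' Pretrain the patch discriminator
#'
#' Trains the discriminator to separate real from generated patches, the
#' fakes coming from a frozen (pretrained) generator.  Returns the
#' best-training-loss checkpoint; with `epochs = 0` the initialized weights
#' are returned unchanged.
#'
#' @inheritParams train_generator_only
#' @param generator a `unet_generator` or generator checkpoint (frozen).
#' @param disc_cfg a [discriminator_config()].
#' @return A list with `checkpoint` (`model_checkpoint` of the
#'   discriminator) and `history`.
#' @export
pretrain_discriminator <- function(pairs, generator, disc_cfg,
                                   train_cfg = train_config()) {
  if (inherits(generator, "model_checkpoint"))
    generator <- restore_model(generator)
  disc <- build_discriminator(disc_cfg)
  if (train_cfg$epochs == 0L)
    return(list(checkpoint = checkpoint(disc, epoch = 0L), history = NULL))
  n <- length(pairs)
  d <- dim(vol_values(pairs[[1L]]$t1ce))
  lat <- list(patch_size = disc_cfg$patch_size,
              stride = default_patch_lattice(d, train_cfg)$stride)
  # frozen fakes, patch lattices in network convention
  cond <- lapply(pairs, function(p)
    extract_patches(to_net3(vol_values(p$t1ce)), lat$patch_size, lat$stride))
  real <- lapply(pairs, function(p)
    extract_patches(to_net3(vol_values(p$t1nce)), lat$patch_size, lat$stride))
  fake <- lapply(pairs, function(p) {
    f <- translate_volume(generator, p$t1ce)
    extract_patches(to_net3(f$values), lat$patch_size, lat$stride)
  })
  state <- adam_init(disc$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  best <- list(loss = Inf, ckpt = checkpoint(disc, epoch = 0L))
  sl <- train_cfg$soft_labels

  with_seed(train_cfg$seed, {
    for (e in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (i in ord) {
        np <- length(cond[[i]]$patches)
        terms <- NULL
        preal <- pfake <- numeric(np)
        for (j in seq_len(np)) {
          cpj <- ad_const(add_ch(cond[[i]]$patches[[j]]))
          sr <- disc$forward(cpj, ad_const(add_ch(real[[i]]$patches[[j]])))
          sf <- disc$forward(cpj, ad_const(add_ch(fake[[i]]$patches[[j]])))
          preal[j] <- sr$value; pfake[j] <- sf$value
          lt <- disc_loss_node(sr, sf, train_cfg,
                               draw_soft_label("real", sl),
                               draw_soft_label("fake", sl))
          terms <- if (is.null(terms)) lt else ad_add(terms, lt)
        }
        loss <- ad_scale(terms, 1 / np)
        ad_backward(loss)
        state <- adam_step(disc$params, state, lr = train_cfg$lr,
                           beta1 = train_cfg$beta1, beta2 = train_cfg$beta2)
        losses <- c(losses, loss$value)
      }
      el <- mean(check_finite_loss(losses, "discriminator"))
      history <- rbind(history, data.frame(epoch = e, loss = el))
      if (el < best$loss)
        best <- list(loss = el, ckpt = checkpoint(disc, epoch = e, loss = el))
    }
  })
  list(checkpoint = best$ckpt, history = history)
}

# network-convention helper on bare 3D arrays
to_net3 <- function(v) (2 * v - 1) * net_headroom
add_ch <- function(v) { if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L); v }

# Differentiable per-patch discriminator loss (0.5 real + 0.5 fake term).
disc_loss_node <- function(s_real, s_fake, cfg, lab_real, lab_fake) {
  if (cfg$loss_mode == "least_squares") {
    ad_add(ad_scale(ad_mean_sq(s_real, lab_real), 0.5),
           ad_scale(ad_mean_sq(s_fake, lab_fake), 0.5))
  } else {
    ad_add(ad_scale(ad_log(s_real, cfg$eps), -0.5),
           ad_scale(ad_log(ad_sub(1, s_fake), cfg$eps), -0.5))
  }
}

# Differentiable adversarial term of the generator loss for one score.
gen_adv_node <- function(s_fake, cfg, lab_real) {
  if (cfg$loss_mode == "least_squares") ad_mean_sq(s_fake, lab_real)
  else ad_scale(ad_log(s_fake, cfg$eps), -1)
}

#' Adversarial (conditional GAN) training
#'
#' Joint training of a pretrained generator and pretrained discriminator
#' (the warm-start protocol): per volume, one discriminator update on
#' real/generated patch pairs with soft labels, then one generator update
#' on `adversarial_term + lambda * L1`.  Batch size 1.  The generator
#' checkpoint with the best (lowest) mean epoch `L_G` is returned.
#'
#' @inheritParams train_generator_only
#' @param gen_ckpt,disc_ckpt `model_checkpoint`s of the pretrained
#'   generator and discriminator.
#' @return A list with `checkpoint` (best generator), `disc_checkpoint`
#'   (final discriminator), `model` (final generator) and `history`
#'   (data.frame epoch, L_G, L_D, L1_term, adversarial_term).
#' @export
train_cgan <- function(pairs, gen_ckpt, disc_ckpt,
                       train_cfg = train_config()) {
  stopifnot(inherits(gen_ckpt, "model_checkpoint"),
            inherits(disc_ckpt, "model_checkpoint"))
  gen <- restore_model(gen_ckpt)
  disc <- restore_model(disc_ckpt)
  n <- length(pairs)
  d <- dim(vol_values(pairs[[1L]]$t1ce))
  lat <- list(patch_size = disc$cfg$patch_size,
              stride = default_patch_lattice(d, train_cfg)$stride)
  xs <- lapply(pairs, function(p) to_net(vol_values(p$t1ce)))
  ts <- lapply(pairs, function(p) to_net(vol_values(p$t1nce)))
  org <- extract_patches(array(0, dim = d), lat$patch_size, lat$stride)$origins
  np <- nrow(org)
  ps <- lat$patch_size
  g_state <- adam_init(gen$params)
  d_state <- adam_init(disc$params)
  sl <- train_cfg$soft_labels
  history <- NULL
  best <- list(loss = Inf, ckpt = checkpoint(gen, epoch = 0L))

  crop4 <- function(arr, o) ad_const(
    arr[(o[1L] + 1L):(o[1L] + ps), (o[2L] + 1L):(o[2L] + ps),
        (o[3L] + 1L):(o[3L] + ps), , drop = FALSE])

  with_seed(train_cfg$seed, {
    for (e in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      eg <- ed <- el1 <- eadv <- numeric(0)
      all_pr <- all_pf <- numeric(0)
      for (i in ord) {
        x <- xs[[i]]; t <- ts[[i]]
        # --- discriminator step (generator frozen / detached) ---
        fake_val <- gen$forward(ad_const(x))$value
        dterms <- NULL
        for (j in seq_len(np)) {
          o <- org[j, ]
          sr <- disc$forward(crop4(x, o), crop4(t, o))
          sf <- disc$forward(crop4(x, o),
                             ad_const(fake_val[(o[1L] + 1L):(o[1L] + ps),
                                               (o[2L] + 1L):(o[2L] + ps),
                                               (o[3L] + 1L):(o[3L] + ps), 1L,
                                               drop = FALSE]))
          all_pr <- c(all_pr, sr$value); all_pf <- c(all_pf, sf$value)
          lt <- disc_loss_node(sr, sf, train_cfg,
                               draw_soft_label("real", sl),
                               draw_soft_label("fake", sl))
          dterms <- if (is.null(dterms)) lt else ad_add(dterms, lt)
        }
        d_loss <- ad_scale(dterms, 1 / np)
        ad_backward(d_loss)
        d_state <- adam_step(disc$params, d_state, lr = train_cfg$lr,
                             beta1 = train_cfg$beta1, beta2 = train_cfg$beta2)
        ed <- c(ed, d_loss$value)

        # --- generator step ---
        y <- gen$forward(ad_const(x), train = TRUE)
        l1 <- ad_mean_abs(y, ad_const(t))
        aterms <- NULL
        for (j in seq_len(np)) {
          o <- org[j, ]
          sf <- disc$forward(crop4(x, o), ad_crop(y, o + 1L, rep(ps, 3L)))
          at <- gen_adv_node(sf, train_cfg, draw_soft_label("real", sl))
          aterms <- if (is.null(aterms)) at else ad_add(aterms, at)
        }
        adv <- ad_scale(aterms, 1 / np)
        g_loss <- ad_add(adv, ad_scale(l1, train_cfg$l1_weight))
        ad_backward(g_loss)
        ad_zero_grad(disc$params)   # D saw gradients through the G step
        g_state <- adam_step(gen$params, g_state, lr = train_cfg$lr,
                             beta1 = train_cfg$beta1, beta2 = train_cfg$beta2)
        eg <- c(eg, g_loss$value); el1 <- c(el1, l1$value)
        eadv <- c(eadv, adv$value)
      }
      check_finite_loss(c(eg, ed), "cGAN")
      if (length(all_pr) > 1L && stats::sd(all_pr) < 1e-4 &&
          stats::sd(all_pf) < 1e-4 &&
          abs(mean(all_pr) - mean(all_pf)) < 1e-3)
        warning("discriminator collapse: near-constant scores in epoch ", e)
      rec <- data.frame(epoch = e, L_G = mean(eg), L_D = mean(ed),
                        L1_term = mean(el1), adversarial_term = mean(eadv))
      history <- rbind(history, rec)
      if (rec$L_G < best$loss)
        best <- list(loss = rec$L_G,
                     ckpt = checkpoint(gen, epoch = e, loss = rec$L_G))
    }
  })
  list(checkpoint = best$ckpt, disc_checkpoint = checkpoint(disc),
       model = gen, history = history)
}
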