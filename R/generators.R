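#' Generator configuration
#'
#' Describes one of the three 3D U-Net-like translation generators:
#'
#' * `res`: descending blocks of strided 3D convolution + instance
#'   normalization + LeakyReLU(alpha), each followed by a residual module of
#'   1-3 (conv + LeakyReLU) blocks with additive skip; ascending blocks of
#'   transposed convolution + ReLU with long (concatenation) skip
#'   connections; final layer upsample x2 + convolution + tanh.
#' * `att`: descending blocks of two (conv + norm + ReLU) with 2x2x2 max
#'   pooling between levels; ascending blocks of upsample x2 + conv + ReLU,
#'   an attention gate on the skip features, and two conv + ReLU; final
#'   1x1x1 convolution + tanh.
#' * `trans`: four strided convolutional descending blocks, a linear
#'   projection of the bottleneck features to token embeddings, four
#'   transformer layers (multi-head self-attention + feed-forward, residual
#'   connections), reshaping, and ascending blocks with transposed
#'   convolutions; final 1x1x1 convolution + tanh.
#'
#' All variants map a single-channel volume in `[-1, 1]` to a same-shape
#' volume in `[-1, 1]` (the tanh range); the data loader maps `[0, 1]`
#' intensities to `[-1, 1]` and back.  Channel width doubles per level from
#' `base_channels`.  Convolution weights are initialized N(0, 0.02), seeded.
#'
#' @param variant `"res"`, `"att"` or `"trans"`.
#' @param input_shape three integers, each divisible by `2^depth`.
#' @param depth number of descending blocks (reference scale: 5 for
#'   res/att, 4 for trans; the default adapts to small grids).
#' @param base_channels channels of the first level.
#' @param residual_blocks_per_level 1-3 residual blocks (res variant).
#' @param conv_blocks_per_level inner conv blocks per level (trans variant).
#' @param n_transformer_layers transformer layers in the bottleneck.
#' @param n_attention_heads attention heads (must divide `embed_dim`).
#' @param embed_dim token embedding width; default twice the bottleneck
#'   channel count.
#' @param alpha LeakyReLU negative slope.
#' @param seed integer seed for weight initialization.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(variant = c("res", "att", "trans"),
                             input_shape = c(32L, 32L, 32L),
                             depth = NULL,
                             base_channels = 8L,
                             residual_blocks_per_level = 1L,
                             conv_blocks_per_level = 1L,
                             n_transformer_layers = 4L,
                             n_attention_heads = 4L,
                             embed_dim = NULL,
                             alpha = 0.2,
                             seed = 1L) {
  variant <- match.arg(variant)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 4L))
    stop("`input_shape` must be 3 integers >= 4")
  if (is.null(depth)) {
    ref <- if (variant == "trans") 4L else 5L
    depth <- min(ref, floor(log2(min(input_shape))))
  }
  depth <- as.integer(depth)
  if (depth < 2L) stop("`depth` must be >= 2")
  if (any(input_shape %% (2L^depth) != 0L))
    stop("input_shape (", paste(input_shape, collapse = "x"),
         ") must be divisible by 2^depth = ", 2L^depth)
  if (!residual_blocks_per_level %in% 1:3)
    stop("`residual_blocks_per_level` must be 1, 2 or 3")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  ch <- as.integer(base_channels * 2L^(seq_len(depth) - 1L))
  if (is.null(embed_dim)) embed_dim <- 2L * ch[depth]
  embed_dim <- as.integer(embed_dim)
  if (variant == "trans") {
    if (embed_dim %% n_attention_heads != 0L)
      stop("`embed_dim` must be divisible by `n_attention_heads`")
    n_tokens <- prod(input_shape %/% 2L^depth)
    if (n_tokens > 4096L)
      stop("token count ", n_tokens, " too large for the configured ",
           "embedding; increase depth or reduce input_shape")
  }
  structure(list(variant = variant, input_shape = input_shape, depth = depth,
                 base_channels = as.integer(base_channels), channels = ch,
                 residual_blocks_per_level = as.integer(residual_blocks_per_level),
                 conv_blocks_per_level = as.integer(conv_blocks_per_level),
                 n_transformer_layers = as.integer(n_transformer_layers),
                 n_attention_heads = as.integer(n_attention_heads),
                 embed_dim = embed_dim, alpha = alpha,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## ---- parameter store --------------------------------------------------------

new_param_store <- function() {
  st <- new.env(parent = emptyenv())
  st$params <- list()
  st
}

# Conv weights N(0, 0.02), biases zero, norm scale 1 / shift 0.
st_conv <- function(st, name, k, cin, cout) {
  st$params[[paste0(name, ".w")]] <-
    ad_param(array(stats::rnorm(k^3 * cin * cout, 0, 0.02),
                   dim = c(k, k, k, cin, cout)))
  st$params[[paste0(name, ".b")]] <- ad_param(numeric(cout))
}

# Transposed conv: weight stored output->input, dim c(k,k,k,cout,cin).
st_convT <- function(st, name, k, cin, cout) {
  st$params[[paste0(name, ".w")]] <-
    ad_param(array(stats::rnorm(k^3 * cin * cout, 0, 0.02),
                   dim = c(k, k, k, cout, cin)))
  st$params[[paste0(name, ".b")]] <- ad_param(numeric(cout))
}

st_norm <- function(st, name, c) {
  st$params[[paste0(name, ".g")]] <- ad_param(rep(1, c))
  st$params[[paste0(name, ".be")]] <- ad_param(numeric(c))
}

st_linear <- function(st, name, din, dout, sd = 0.02) {
  st$params[[paste0(name, ".w")]] <-
    ad_param(matrix(stats::rnorm(din * dout, 0, sd), din, dout))
  st$params[[paste0(name, ".b")]] <- ad_param(numeric(dout))
}

# Lookup helpers used by the forward closures.
pget <- function(P, name) P[[name]] %||% stop("missing parameter ", name)

fwd_conv <- function(P, name, x, stride = 1L, pad = 1L)
  ad_conv3d(x, pget(P, paste0(name, ".w")), pget(P, paste0(name, ".b")),
            stride, pad)

fwd_convT <- function(P, name, x, stride = 2L, pad = 1L)
  ad_conv3d_transpose(x, pget(P, paste0(name, ".w")),
                      pget(P, paste0(name, ".b")), stride, pad)

fwd_norm <- function(P, name, x)
  ad_channel_norm(x, pget(P, paste0(name, ".g")), pget(P, paste0(name, ".be")))

fwd_linear <- function(P, name, x)
  ad_linear(x, pget(P, paste0(name, ".w")), pget(P, paste0(name, ".b")))

as_input_node <- function(x) {
  if (inherits(x, "ad_node")) return(x)
  v <- vol_values(x)
  if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L)
  ad_const(v)
}

## ---- attention gate ---------------------------------------------------------

#' Attention gate parameters
#'
#' Creates the weights of one additive attention gate: a 1x1x1 convolution
#' on the skip features `x`, a 1x1x1 convolution on the gating features
#' `g`, a ReLU, a 1x1x1 convolution to one channel and a sigmoid.  The skip
#' features are multiplied element-wise by the resulting coefficient map
#' (values in (0, 1)).
#'
#' @param c_x channels of the gated (skip) features.
#' @param c_g channels of the gating features.
#' @param c_inter intermediate channels (default `max(1, c_x %/% 2)`).
#' @param seed integer seed for the weight draw.
#' @return A named list of parameter arrays of class `attention_gate_params`.
#' @export
attention_gate_params <- function(c_x, c_g, c_inter = max(1L, c_x %/% 2L),
                                  seed = 1L) {
  st <- new_param_store()
  with_seed(seed, {
    st_conv(st, "ax", 1L, c_x, c_inter)
    st_conv(st, "ag", 1L, c_g, c_inter)
    st_conv(st, "psi", 1L, c_inter, 1L)
  })
  structure(st$params, class = "attention_gate_params")
}

# Node-level gate used inside the att generator.  Returns list(out, coef).
gate_forward <- function(P, prefix, x, g) {
  a <- ad_add(fwd_conv(P, paste0(prefix, "ax"), x, 1L, 0L),
              fwd_conv(P, paste0(prefix, "ag"), g, 1L, 0L))
  coef <- ad_sigmoid(fwd_conv(P, paste0(prefix, "psi"), ad_relu(a), 1L, 0L))
  list(out = ad_bcast_mul(x, coef), coef = coef)
}

#' Apply an attention gate
#'
#' Computes `sigmoid(conv(ReLU(conv(x) + conv(g))))` and multiplies the
#' skip features `x` element-wise by the resulting coefficients.
#'
#' @param x skip features: array `c(D, H, W, C_x)` (a 3D array is treated
#'   as one channel).
#' @param g gating features on the same spatial grid, `c(D, H, W, C_g)`.
#' @param gate an [attention_gate_params()] object.
#' @return A list with `output` (same shape as `x`) and `coefficients`
#'   (single-channel array with values in (0, 1)).
#' @export
attention_gate <- function(x, g, gate) {
  stopifnot(inherits(gate, "attention_gate_params"))
  fix <- function(v) { if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L); v }
  x <- fix(vol_values(x)); g <- fix(vol_values(g))
  if (!all(dim(x)[1:3] == dim(g)[1:3]))
    stop("x and g must share one spatial grid")
  if (dim(x)[4L] != dim(gate$ax.w$value)[4L] ||
      dim(g)[4L] != dim(gate$ag.w$value)[4L])
    stop("channel mismatch between inputs and gate parameters")
  P <- gate
  res <- gate_forward(P, "", ad_const(x), ad_const(g))
  list(output = res$out$value, coefficients = res$coef$value)
}

## ---- builders ---------------------------------------------------------------

make_generator <- function(cfg, params, forward) {
  structure(list(cfg = cfg, params = params, forward = forward,
                 diagnostics = new.env(parent = emptyenv())),
            class = "unet_generator")
}

#' @export
print.unet_generator <- function(x, ...) {
  cat(sprintf("<unet_generator> variant=%s depth=%d base=%d input=%s params=%d\n",
              x$cfg$variant, x$cfg$depth, x$cfg$base_channels,
              paste(x$cfg$input_shape, collapse = "x"), n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a generator or discriminator model object.
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' Build a generator
#'
#' Dispatches to [build_res_unet()], [build_att_unet()] or
#' [build_trans_unet()] according to `cfg$variant`.
#'
#' @param cfg a [generator_config()].
#' @return A `unet_generator`: list with `cfg`, `params` (named parameter
#'   nodes) and `forward(x)` mapping a `c(D, H, W, 1)` input (array,
#'   [volume3d()] in `[-1, 1]`, or autodiff node) to a same-shape node.
#' @export
build_generator <- function(cfg) {
  switch(cfg$variant,
         res = build_res_unet(cfg),
         att = build_att_unet(cfg),
         trans = build_trans_unet(cfg))
}

#' @rdname build_generator
#' @export
build_res_unet <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"), cfg$variant == "res")
  ch <- cfg$channels
  d <- cfg$depth
  nres <- cfg$residual_blocks_per_level
  st <- new_param_store()
  with_seed(cfg$seed, {
    for (l in seq_len(d)) {
      cin <- if (l == 1L) 1L else ch[l - 1L]
      st_conv(st, sprintf("down%d", l), 4L, cin, ch[l])
      st_norm(st, sprintf("dnorm%d", l), ch[l])
      for (j in seq_len(nres))
        st_conv(st, sprintf("dres%d_%d", l, j), 3L, ch[l], ch[l])
    }
    for (l in seq_len(d - 1L)) {
      st_convT(st, sprintf("up%d", l), 4L, ch[l + 1L], ch[l])
      st_norm(st, sprintf("unorm%d", l), ch[l])
      st_conv(st, sprintf("fuse%d", l), 3L, 2L * ch[l], ch[l])
      st_norm(st, sprintf("fnorm%d", l), ch[l])
      for (j in seq_len(nres))
        st_conv(st, sprintf("ures%d_%d", l, j), 3L, ch[l], ch[l])
    }
    st_conv(st, "final", 3L, ch[1L], 1L)
  })
  P <- st$params
  a <- cfg$alpha

  res_module <- function(h, prefix) {
    m <- h
    for (j in seq_len(nres))
      m <- ad_leaky_relu(fwd_conv(P, sprintf("%s_%d", prefix, j), m), a)
    ad_add(h, m)
  }

  forward <- function(x, train = FALSE) {
    h <- as_input_node(x)
    enc <- vector("list", d)
    for (l in seq_len(d)) {
      h <- ad_leaky_relu(fwd_norm(P, sprintf("dnorm%d", l),
                                  fwd_conv(P, sprintf("down%d", l), h, 2L, 1L)), a)
      h <- res_module(h, sprintf("dres%d", l))
      enc[[l]] <- h
    }
    for (l in seq(d - 1L, 1L)) {
      h <- ad_relu(fwd_norm(P, sprintf("unorm%d", l),
                            fwd_convT(P, sprintf("up%d", l), h)))
      h <- ad_concat(h, enc[[l]])
      h <- ad_leaky_relu(fwd_norm(P, sprintf("fnorm%d", l),
                                  fwd_conv(P, sprintf("fuse%d", l), h)), a)
      h <- res_module(h, sprintf("ures%d", l))
    }
    ad_tanh(fwd_conv(P, "final", ad_upsample2(h)))
  }
  make_generator(cfg, P, forward)
}

#' @rdname build_generator
#' @export
build_att_unet <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"), cfg$variant == "att")
  ch <- cfg$channels
  d <- cfg$depth
  st <- new_param_store()
  with_seed(cfg$seed, {
    for (l in seq_len(d)) {
      cin <- if (l == 1L) 1L else ch[l - 1L]
      st_conv(st, sprintf("enc%da", l), 3L, cin, ch[l])
      st_norm(st, sprintf("enc%dan", l), ch[l])
      st_conv(st, sprintf("enc%db", l), 3L, ch[l], ch[l])
      st_norm(st, sprintf("enc%dbn", l), ch[l])
    }
    for (l in seq_len(d - 1L)) {
      st_conv(st, sprintf("dec%dup", l), 3L, ch[l + 1L], ch[l])
      st_norm(st, sprintf("dec%dupn", l), ch[l])
      ci <- max(1L, ch[l] %/% 2L)
      st_conv(st, sprintf("gate%d.ax", l), 1L, ch[l], ci)
      st_conv(st, sprintf("gate%d.ag", l), 1L, ch[l], ci)
      st_conv(st, sprintf("gate%d.psi", l), 1L, ci, 1L)
      st_conv(st, sprintf("dec%da", l), 3L, 2L * ch[l], ch[l])
      st_norm(st, sprintf("dec%dan", l), ch[l])
      st_conv(st, sprintf("dec%db", l), 3L, ch[l], ch[l])
      st_norm(st, sprintf("dec%dbn", l), ch[l])
    }
    st_conv(st, "final", 1L, ch[1L], 1L)
  })
  P <- st$params

  model <- NULL
  forward <- function(x, train = FALSE) {
    h <- as_input_node(x)
    enc <- vector("list", d)
    for (l in seq_len(d)) {
      if (l > 1L) h <- ad_maxpool2(h)
      h <- ad_relu(fwd_norm(P, sprintf("enc%dan", l),
                            fwd_conv(P, sprintf("enc%da", l), h)))
      h <- ad_relu(fwd_norm(P, sprintf("enc%dbn", l),
                            fwd_conv(P, sprintf("enc%db", l), h)))
      enc[[l]] <- h
    }
    coefs <- vector("list", d - 1L)
    for (l in seq(d - 1L, 1L)) {
      g <- ad_relu(fwd_norm(P, sprintf("dec%dupn", l),
                            fwd_conv(P, sprintf("dec%dup", l),
                                     ad_upsample2(h))))
      gt <- gate_forward(P, sprintf("gate%d.", l), enc[[l]], g)
      coefs[[l]] <- gt$coef$value
      h <- ad_concat(g, gt$out)
      h <- ad_relu(fwd_norm(P, sprintf("dec%dan", l),
                            fwd_conv(P, sprintf("dec%da", l), h)))
      h <- ad_relu(fwd_norm(P, sprintf("dec%dbn", l),
                            fwd_conv(P, sprintf("dec%db", l), h)))
    }
    model$diagnostics$gate_coefficients <- coefs
    ad_tanh(fwd_conv(P, "final", h, 1L, 0L))
  }
  model <- make_generator(cfg, P, forward)
  model
}

#' @rdname build_generator
#' @export
build_trans_unet <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"), cfg$variant == "trans")
  ch <- cfg$channels
  d <- cfg$depth
  E <- cfg$embed_dim
  nh <- cfg$n_attention_heads
  dh <- E %/% nh
  nlayers <- cfg$n_transformer_layers
  ninner <- cfg$conv_blocks_per_level
  st <- new_param_store()
  with_seed(cfg$seed, {
    for (l in seq_len(d)) {
      cin <- if (l == 1L) 1L else ch[l - 1L]
      st_conv(st, sprintf("enc%d", l), 3L, cin, ch[l])
      for (j in seq_len(ninner)) {
        st_norm(st, sprintf("enc%dn%d", l, j), ch[l])
        st_conv(st, sprintf("enc%dc%d", l, j), 3L, ch[l], ch[l])
      }
    }
    st_linear(st, "proj_in", ch[d], E)
    for (i in seq_len(nlayers)) {
      for (nm in c("wq", "wk", "wv", "wo"))
        st_linear(st, sprintf("t%d.%s", i, nm), E, E)
      st_linear(st, sprintf("t%d.ff1", i), E, 2L * E)
      st_linear(st, sprintf("t%d.ff2", i), 2L * E, E)
    }
    st_linear(st, "proj_out", E, ch[d])
    for (l in seq(d, 1L)) {
      st_conv(st, sprintf("dec%d", l), 3L, ch[l], ch[l])
      st_norm(st, sprintf("dec%dn", l), ch[l])
      cout <- if (l > 1L) ch[l - 1L] else ch[1L]
      st_convT(st, sprintf("dec%dT", l), 4L, ch[l], cout)
    }
    st_conv(st, "final", 1L, ch[1L], 1L)
  })
  P <- st$params
  bshape <- cfg$input_shape %/% 2L^d
  n_tok <- prod(bshape)

  model <- NULL
  transformer_layer <- function(X, i, attn_store) {
    Q <- fwd_linear(P, sprintf("t%d.wq", i), X)
    K <- fwd_linear(P, sprintf("t%d.wk", i), X)
    V <- fwd_linear(P, sprintf("t%d.wv", i), X)
    heads <- NULL
    for (h in seq_len(nh)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      A <- ad_softmax_rows(
        ad_scale(ad_matmul(ad_cols(Q, idx), ad_transpose(ad_cols(K, idx))),
                 1 / sqrt(dh)))
      attn_store[[length(attn_store) + 1L]] <- A$value
      o <- ad_matmul(A, ad_cols(V, idx))
      heads <- if (is.null(heads)) o else ad_cbind2(heads, o)
    }
    X <- ad_add(X, fwd_linear(P, sprintf("t%d.wo", i), heads))
    ff <- fwd_linear(P, sprintf("t%d.ff2", i),
                     ad_relu(fwd_linear(P, sprintf("t%d.ff1", i), X)))
    list(x = ad_add(X, ff), attn = attn_store)
  }

  forward <- function(x, train = FALSE) {
    h <- as_input_node(x)
    for (l in seq_len(d)) {
      h <- ad_relu(fwd_conv(P, sprintf("enc%d", l), h, 2L, 1L))
      for (j in seq_len(ninner)) {
        h <- fwd_conv(P, sprintf("enc%dc%d", l, j),
                      ad_relu(fwd_norm(P, sprintf("enc%dn%d", l, j), h)))
      }
    }
    X <- fwd_linear(P, "proj_in", ad_reshape(h, c(n_tok, ch[d])))
    model$diagnostics$tokens_in <- X$value
    attn <- list()
    for (i in seq_len(nlayers)) {
      res <- transformer_layer(X, i, attn)
      X <- res$x
      attn <- res$attn
    }
    model$diagnostics$attention <- attn
    model$diagnostics$tokens_out <- X$value
    h <- ad_reshape(fwd_linear(P, "proj_out", X), c(bshape, ch[d]))
    for (l in seq(d, 1L)) {
      h <- ad_relu(fwd_norm(P, sprintf("dec%dn", l),
                            fwd_conv(P, sprintf("dec%d", l), h)))
      h <- ad_relu(fwd_convT(P, sprintf("dec%dT", l), h))
    }
    ad_tanh(fwd_conv(P, "final", h, 1L, 0L))
  }
  model <- make_generator(cfg, P, forward)
  model
}

## ---- inference and checkpoints ---------------------------------------------

#' Translate one volume with a generator
#'
#' Maps the `[0, 1]` input to the network's `[-1, 1]` convention, runs the
#' forward pass and maps back, clipping to `[0, 1]`.
#'
#' @param model a `unet_generator` or a checkpoint from [checkpoint()].
#' @param vol a [volume3d()] (or 3D array) with intensities in `[0, 1]`.
#' @return A [volume3d()] with the synthesized intensities.
#' @export
translate_volume <- function(model, vol) {
  if (inherits(model, "model_checkpoint")) model <- restore_model(model)
  vol <- as_volume3d(vol)
  y <- model$forward(ad_const(to_net(vol$values)))$value
  volume3d(clip01(from_net(array(y, dim = dim(y)[1:3]))), vol$voxel_size_mm)
}

# [0,1] intensities map to [-0.9, 0.9]: the 10% headroom keeps targets away
# from the tanh asymptotes so the gradient cannot die on constant regions
# (background is the majority class of a head-sized field of view).
net_headroom <- 0.9

to_net <- function(v) {
  x <- (2 * v - 1) * net_headroom
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

from_net <- function(v) (v / net_headroom + 1) / 2

#' Model checkpoints
#'
#' `checkpoint()` captures a model's configuration and parameter values
#' (plus optional metadata such as the epoch and loss); `restore_model()`
#' rebuilds the model and restores the captured values;
#' `save_checkpoint()` / `load_checkpoint()` serialize to disk.
#'
#' @param model a `unet_generator` or `patch_discriminator`.
#' @param ... named metadata stored alongside (epoch, loss, ...).
#' @return `checkpoint()` a `model_checkpoint`; `restore_model()` the
#'   rebuilt model.
#' @export
checkpoint <- function(model, ...) {
  structure(list(kind = class(model)[1L], cfg = model$cfg,
                 values = lapply(model$params, function(p) p$value),
                 meta = list(...)),
            class = "model_checkpoint")
}

#' @param ckpt a `model_checkpoint`.
#' @rdname checkpoint
#' @export
restore_model <- function(ckpt) {
  stopifnot(inherits(ckpt, "model_checkpoint"))
  model <- if (ckpt$kind == "patch_discriminator")
    build_discriminator(ckpt$cfg) else build_generator(ckpt$cfg)
  stopifnot(identical(names(model$params), names(ckpt$values)))
  for (nm in names(ckpt$values)) model$params[[nm]]$value <- ckpt$values[[nm]]
  model
}

#' @param path file path for the serialized checkpoint.
#' @rdname checkpoint
#' @export
save_checkpoint <- function(ckpt, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
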