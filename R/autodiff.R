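# Reverse-mode automatic differentiation on plain R arrays.
#
# Each ad_node holds a value, its parent nodes and a backward closure that
# maps the node's upstream gradient to gradients for each parent.  Graphs
# are rebuilt at every forward pass; parameter nodes (param = TRUE) persist
# across passes and accumulate gradients in $grad.  Feature maps are
# channel-last arrays dim = c(D, H, W, C); token matrices are n x d.

ad_node <- function(value, parents = list(), backfn = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$param <- param
  e$grad <- NULL
  e$needs <- param || any(vapply(parents, function(p) p$needs, logical(1)))
  e$id <- ad_state$next_id
  ad_state$next_id <- ad_state$next_id + 1L
  class(e) <- "ad_node"
  e
}

ad_param <- function(value) ad_node(value, param = TRUE)
ad_const <- function(value) ad_node(value)

as_ad <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# Depth-first topological order over nodes that need gradients.
ad_toposort <- function(root) {
  order <- vector("list", 256L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  visit <- function(node) {
    key <- as.character(node$id)
    if (!is.null(visited[[key]])) return(invisible())
    visited[[key]] <- TRUE
    for (p in node$parents) if (p$needs) visit(p)
    n_ord <<- n_ord + 1L
    if (n_ord > length(order)) length(order) <<- 2L * n_ord
    order[[n_ord]] <<- node
  }
  visit(root)
  order[seq_len(n_ord)]
}

ad_state <- new.env(parent = emptyenv())
ad_state$next_id <- 1L

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backpropagate from a scalar loss node; fills $grad on parameter nodes
# (and every intermediate node that needs a gradient).
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "ad_node"), length(loss$value) == 1L)
  if (!loss$needs) return(invisible())
  order <- ad_toposort(loss)
  loss$grad <- 1
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    pgrads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$needs || is.null(pgrads[[j]])) next
      p$grad <- if (is.null(p$grad)) pgrads[[j]] else p$grad + pgrads[[j]]
    }
    if (!node$param) node$grad <- NULL  # free intermediate gradients
  }
  invisible(loss)
}

## ---- elementwise ops -------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g) {
    ga <- if (length(a$value) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$value) == 1L && length(g) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b), function(g) {
    ga <- if (length(a$value) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$value) == 1L && length(g) > 1L) sum(-g) else -g
    list(ga, gb)
  })
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value * b$value, list(a, b), function(g) {
    ga <- g * b$value
    gb <- g * a$value
    if (length(a$value) == 1L && length(g) > 1L) ga <- sum(ga)
    if (length(b$value) == 1L && length(g) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ad_scale <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  ad_node(pmax(a$value, 0), list(a), function(g) list(g * (a$value > 0)))
}

ad_leaky_relu <- function(a, alpha = 0.2) {
  a <- as_ad(a)
  m <- ifelse(a$value > 0, 1, alpha)
  y <- a$value * m
  if (!is.null(dim(a$value))) dim(y) <- dim(a$value)
  ad_node(y, list(a), function(g) list(g * m))
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  y <- tanh(a$value)
  ad_node(y, list(a), function(g) list(g * (1 - y^2)))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  y <- 1 / (1 + exp(-a$value))
  ad_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_log <- function(a, eps = 1e-7) {
  a <- as_ad(a)
  v <- pmax(a$value, eps)
  ad_node(log(v), list(a), function(g) list(g / v * (a$value >= eps)))
}

## ---- reductions and losses -------------------------------------------------

ad_mean <- function(a) {
  a <- as_ad(a)
  n <- length(a$value)
  ad_node(mean(a$value), list(a), function(g) {
    ga <- array(g / n, dim = dim(a$value) %||% n)
    list(ga)
  })
}

# mean(|a - b|): the L1 training objective.
ad_mean_abs <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  d <- a$value - b$value
  n <- length(d)
  ad_node(mean(abs(d)), list(a, b), function(g) {
    ga <- g * sign(d) / n
    list(ga, -ga)
  })
}

ad_mean_sq <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  d <- a$value - b$value
  n <- length(d)
  ad_node(mean(d^2), list(a, b), function(g) {
    ga <- g * 2 * d / n
    list(ga, -ga)
  })
}

## ---- convolution and spatial ops ------------------------------------------

conv_out_len <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# 3D convolution: x dim c(D,H,W,Cin), w dim c(k,k,k,Cin,Cout), b length Cout.
# The im2col patch matrix from the forward pass is kept for the weight
# gradient and released after the backward pass.
ad_conv3d <- function(x, w, b, stride = 1L, pad = 1L) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xv <- x$value; wv <- w$value
  dims <- dim(xv)
  k <- dim(wv)[1L]; cin <- dim(wv)[4L]; cout <- dim(wv)[5L]
  stopifnot(dims[4L] == cin)
  cols <- .im2col3d(xv, as.integer(dims), as.integer(k),
                    as.integer(stride), as.integer(pad))     # N x (k3*cin)
  wm <- matrix(wv, nrow = k^3 * cin)                         # (k3*cin) x cout
  ym <- cols %*% wm                                          # N x cout
  od <- conv_out_len(dims[1:3], k, stride, pad)
  yv <- array(ym + rep(b$value, each = nrow(ym)), dim = c(od, cout))
  ad_node(yv, list(x, w, b), function(g) {
    gm <- matrix(g, ncol = cout)                             # N x cout
    dx <- .col2im3d(tcrossprod(gm, wm), as.integer(dims), as.integer(k),
                    as.integer(stride), as.integer(pad))
    dw <- array(crossprod(cols, gm), dim = dim(wv))
    cols <<- NULL                                            # free the cache
    db <- colSums(gm)
    list(dx, dw, db)
  })
}

# Transposed 3D convolution (stride-s upsampling).  The weight is stored as
# the weight of the conv that maps output -> input: dim c(k,k,k,Cout,Cin).
# Output spatial size = (in - 1)*stride - 2*pad + k.
ad_conv3d_transpose <- function(x, w, b, stride = 2L, pad = 1L) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xv <- x$value; wv <- w$value
  dims <- dim(xv)
  k <- dim(wv)[1L]; cout <- dim(wv)[4L]; cin <- dim(wv)[5L]
  stopifnot(dims[4L] == cin)
  odims <- (dims[1:3] - 1L) * stride - 2L * pad + k
  wm <- matrix(wv, nrow = k^3 * cout)       # (k3*cout) x cin
  xm <- matrix(xv, ncol = cin)              # N_in x cin
  cols <- tcrossprod(xm, wm)                # N_in x (k3*cout)
  yv <- .col2im3d(cols, as.integer(c(odims, cout)), as.integer(k),
                  as.integer(stride), as.integer(pad))
  yv <- yv + rep(b$value, each = prod(odims))
  ad_node(yv, list(x, w, b), function(g) {
    gcols <- .im2col3d(g, as.integer(c(odims, cout)), as.integer(k),
                       as.integer(stride), as.integer(pad))  # N_in x (k3*cout)
    dx <- array(gcols %*% wm, dim = dims)
    dw <- array(crossprod(gcols, xm), dim = dim(wv))
    db <- colSums(matrix(g, ncol = cout))
    list(dx, dw, db)
  })
}

# 2x2x2 max pooling, stride 2.
ad_maxpool2 <- function(x) {
  x <- as_ad(x)
  res <- .maxpool3d2(x$value, as.integer(dim(x$value)))
  ad_node(res$values, list(x), function(g) {
    dx <- numeric(length(x$value))
    dx[res$argmax] <- g
    dim(dx) <- dim(x$value)
    list(dx)
  })
}

# Nearest-neighbour upsampling by a factor of 2 per spatial axis.
ad_upsample2 <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  id <- rep(seq_len(d[1L]), each = 2L)
  ih <- rep(seq_len(d[2L]), each = 2L)
  iw <- rep(seq_len(d[3L]), each = 2L)
  yv <- x$value[id, ih, iw, , drop = FALSE]
  ad_node(yv, list(x), function(g) {
    dx <- array(0, dim = d)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      dx <- dx + g[seq(1L + a, 2L * d[1L], 2L),
                   seq(1L + b, 2L * d[2L], 2L),
                   seq(1L + cc, 2L * d[3L], 2L), , drop = FALSE]
    list(dx)
  })
}

# Channel concatenation (channel is the last, column-major-slowest axis).
ad_concat <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:3] == db[1:3]))
  yv <- array(c(a$value, b$value), dim = c(da[1:3], da[4L] + db[4L]))
  ad_node(yv, list(a, b), function(g) {
    list(array(g[, , , seq_len(da[4L]), drop = FALSE], dim = da),
         array(g[, , , da[4L] + seq_len(db[4L]), drop = FALSE], dim = db))
  })
}

# Axis-aligned spatial crop (1-based origin), keeping all channels.
ad_crop <- function(x, origin, size) {
  x <- as_ad(x)
  d <- dim(x$value)
  i1 <- origin[1L]:(origin[1L] + size[1L] - 1L)
  i2 <- origin[2L]:(origin[2L] + size[2L] - 1L)
  i3 <- origin[3L]:(origin[3L] + size[3L] - 1L)
  yv <- x$value[i1, i2, i3, , drop = FALSE]
  ad_node(yv, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[i1, i2, i3, ] <- g
    list(dx)
  })
}

# Per-channel normalization over the spatial dimensions with learnable
# scale/shift.  With one sample per forward pass this covers both the
# instance-norm and (batch-size-1) batch-norm layers of the generators.
ad_channel_norm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$value)
  n <- prod(d[1:3]); C <- d[4L]
  xm <- matrix(x$value, nrow = n)           # n x C
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  s <- sqrt(v + eps)
  xhat <- sweep(xc, 2L, s, "/")
  ym <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_node(array(ym, dim = d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = n)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gmean <- colMeans(gm)
    gxmean <- colMeans(gm * xhat)
    # dx = gamma/s * (g - mean(g) - xhat * mean(g * xhat)) per channel
    dx <- sweep(gm, 2L, gmean) - sweep(xhat, 2L, gxmean, "*")
    dx <- sweep(dx, 2L, gamma$value / s, "*")
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

# Multiply a C-channel feature map x by a single-channel map s (broadcast
# across channels; column-major recycling makes this a plain product).
ad_bcast_mul <- function(x, s) {
  x <- as_ad(x); s <- as_ad(s)
  dx <- dim(x$value); dsv <- dim(s$value)
  stopifnot(all(dx[1:3] == dsv[1:3]), dsv[4L] == 1L)
  sv <- as.vector(s$value)
  yv <- x$value * sv            # recycles s over the channel axis
  ad_node(yv, list(x, s), function(g) {
    gs <- rowSums(matrix(g * x$value, ncol = dx[4L]))
    dim(gs) <- dsv
    list(g * sv, gs)
  })
}

## ---- dense / transformer ops ----------------------------------------------

# Column slice of a matrix (used to split attention heads).
ad_cols <- function(x, idx) {
  x <- as_ad(x)
  d <- dim(x$value)
  ad_node(x$value[, idx, drop = FALSE], list(x), function(g) {
    dx <- matrix(0, d[1L], d[2L])
    dx[, idx] <- g
    list(dx)
  })
}

ad_cbind2 <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  na <- ncol(a$value)
  ad_node(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), crossprod(a$value, g))
  })
}

# Affine layer on token matrices: X (n x din) %*% W (din x dout) + b.
ad_linear <- function(x, w, b) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  yv <- sweep(x$value %*% w$value, 2L, b$value, "+")
  ad_node(yv, list(x, w, b), function(g) {
    list(g %*% t(w$value), crossprod(x$value, g), colSums(g))
  })
}

ad_softmax_rows <- function(x) {
  x <- as_ad(x)
  m <- apply(x$value, 1L, max)
  e <- exp(x$value - m)
  y <- e / rowSums(e)
  ad_node(y, list(x), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

ad_reshape <- function(x, dims) {
  x <- as_ad(x)
  yv <- x$value
  dim(yv) <- dims
  old <- dim(x$value) %||% length(x$value)
  ad_node(yv, list(x), function(g) {
    dim(g) <- old
    list(g)
  })
}

ad_transpose <- function(x) {
  x <- as_ad(x)
  ad_node(t(x$value), list(x), function(g) list(t(g)))
}

## ---- optimizer -------------------------------------------------------------

# Adam state for a flat list of parameter nodes.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, state, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    p$value <- p$value - lr * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
    p$grad <- NULL
  }
  state
}
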