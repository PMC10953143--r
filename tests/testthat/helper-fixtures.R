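# Shared fixtures: small seeded volumes, phantoms and pair sets.

rand_vol <- function(d = c(8, 8, 8), seed = 1, lo = 0, hi = 1) {
  set.seed(seed)
  volume3d(array(runif(prod(d), lo, hi), dim = d))
}

tiny_params <- function(seed = 1, grid = 16, noise = 0.01, ...) {
  phantom_params(grid_shape = rep(grid, 3L), voxel_size_mm = 12,
                 noise_sigma = noise, seed = seed, ...)
}

tiny_pairs <- function(n, grid = 16, noise = 0.01, seed0 = 100) {
  lapply(seq_len(n), function(i)
    as_image_pair(make_phantom(tiny_params(seed = seed0 + i, grid = grid,
                                           noise = noise))))
}

# Numerical-vs-analytic gradient check for a loss built from parameter
# arrays.  `loss_builder` maps a named list of ad_param nodes to a scalar
# node; returns the worst relative error across all parameters.
gradcheck <- function(loss_builder, params, eps = 1e-5) {
  ad_param <- decontrast:::ad_param
  nodes <- lapply(params, ad_param)
  loss <- loss_builder(nodes)
  decontrast:::ad_backward(loss)
  worst <- 0
  for (nm in names(params)) {
    x <- params[[nm]]
    ng <- x * 0
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      p2 <- params
      p2[[nm]] <- xp
      fp <- loss_builder(lapply(p2, ad_param))$value
      p2[[nm]] <- xm
      fm <- loss_builder(lapply(p2, ad_param))$value
      ng[i] <- (fp - fm) / (2 * eps)
    }
    err <- max(abs(ng - nodes[[nm]]$grad)) / max(1e-8, max(abs(ng)))
    worst <- max(worst, err)
  }
  worst
}
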