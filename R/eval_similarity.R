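#' Union of two brain masks
#'
#' Voxelwise OR of two binary masks on the same grid (the evaluation region
#' for the similarity metrics when each image of a pair has its own
#' skull-stripping mask).
#'
#' @param mask_a,mask_b binary arrays (or [volume3d()]) on one grid.
#' @return A logical array.
#' @export
mask_union <- function(mask_a, mask_b) {
  a <- vol_values(mask_a); b <- vol_values(mask_b)
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  (a > 0) | (b > 0)
}

check_metric_inputs <- function(x, y, mask) {
  xv <- vol_values(x); yv <- vol_values(y); mv <- vol_values(mask) > 0
  if (!identical(dim(xv), dim(yv)) || !identical(dim(xv), dim(mv)))
    stop("volumes and mask must share one grid")
  if (!any(mv)) stop("mask is empty")
  list(x = xv, y = yv, mask = mv)
}

#' Mean absolute error within a mask (percent)
#'
#' `100 * mean(|x - y|)` over the mask voxels, for intensities in the
#' `[0, 1]` convention (so the result is a percentage of the intensity
#' range).  Symmetric in its arguments; 0 for identical images.
#'
#' @param x,y volumes on one grid, intensities in `[0, 1]`.
#' @param mask nonempty binary mask on the same grid.
#' @return MAE in percent.
#' @export
mae <- function(x, y, mask) {
  z <- check_metric_inputs(x, y, mask)
  100 * mean(abs(z$x[z$mask] - z$y[z$mask]))
}

#' Peak signal-to-noise ratio within a mask (dB)
#'
#' `10 * log10(data_range^2 / MSE)` over the mask voxels.  Identical images
#' have zero MSE and return `Inf` (the "infinite" optimum).
#'
#' @inheritParams mae
#' @param data_range intensity range of the images (default 1 for min-max
#'   rescaled intensities).
#' @return PSNR in decibels, possibly `Inf`.
#' @export
psnr <- function(x, y, mask, data_range = 1) {
  stopifnot(data_range > 0)
  z <- check_metric_inputs(x, y, mask)
  mse <- mean((z$x[z$mask] - z$y[z$mask])^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# Sliding-window box sums over all fully-contained windows of width w
# (valid region), per axis via cumulative sums.
box_sum_axis <- function(x, w, axis) {
  n <- dim(x)[axis]
  cs <- apply(x, setdiff(1:3, axis), cumsum)
  # apply() puts the summed axis first; move it back
  cs <- aperm(cs, order(c(axis, setdiff(1:3, axis))))
  hi <- slice_axis(cs, w:n, axis)
  lo <- slice_axis(cs, 1:(n - w + 1L) - 1L, axis, zero_pad = TRUE)
  hi - lo
}

slice_axis <- function(x, idx, axis, zero_pad = FALSE) {
  if (zero_pad) {
    # index 0 means "zero" (prefix sum before the first element)
    pos <- idx > 0L
    out <- array(0, dim = replace(dim(x), axis, length(idx)))
    if (any(pos)) {
      sl <- switch(axis,
                   x[idx[pos], , , drop = FALSE],
                   x[, idx[pos], , drop = FALSE],
                   x[, , idx[pos], drop = FALSE])
      switch(axis,
             out[which(pos), , ] <- sl,
             out[, which(pos), ] <- sl,
             out[, , which(pos)] <- sl)
    }
    return(out)
  }
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

box_sum3d <- function(x, w) {
  for (axis in 1:3) x <- box_sum_axis(x, w, axis)
  x
}

#' Structural similarity within a mask
#'
#' Single-scale SSIM with a cubic uniform window, restricted to the mask:
#' intensities outside the mask are zeroed, the SSIM map is computed on
#' every window fully contained in the volume (window statistics use the
#' biased, divide-by-N moments), and the map is averaged over the window
#' centres that fall inside the mask.  Intensities outside the mask
#' therefore never influence the value.  Identical images give 1.
#'
#' @inheritParams psnr
#' @param window odd cubic window edge (default 7).
#' @param K the two stabilizing constants `(K1, K2)`.
#' @return SSIM value (<= 1).
#' @export
ssim <- function(x, y, mask, window = 7L, K = c(0.01, 0.03), data_range = 1) {
  z <- check_metric_inputs(x, y, mask)
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("`window` must be odd")
  if (any(dim(z$x) < window))
    stop("window (", window, ") larger than volume (",
         paste(dim(z$x), collapse = "x"), ")")
  z$x <- z$x * z$mask
  z$y <- z$y * z$mask
  nw <- window^3
  mx <- box_sum3d(z$x, window) / nw
  my <- box_sum3d(z$y, window) / nw
  vx <- box_sum3d(z$x^2, window) / nw - mx^2
  vy <- box_sum3d(z$y^2, window) / nw - my^2
  cxy <- box_sum3d(z$x * z$y, window) / nw - mx * my
  C1 <- (K[1L] * data_range)^2
  C2 <- (K[2L] * data_range)^2
  smap <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  h <- (window - 1L) %/% 2L
  d <- dim(z$x)
  centers <- z$mask[(1L + h):(d[1L] - h), (1L + h):(d[2L] - h),
                    (1L + h):(d[3L] - h), drop = FALSE]
  if (!any(centers))
    stop("mask has no voxels among valid window centres")
  mean(smap[centers])
}

#' Paired t-tests with Bonferroni correction
#'
#' For each named comparison, a two-sided paired t-test on the difference
#' of the paired samples; p-values are Bonferroni-corrected as
#' `min(1, m * p)` over `m` comparisons.  Comparisons with zero-variance
#' differences are flagged degenerate (no test statistic is reported),
#' except the all-zero difference, which is reported as t = 0, p = 1.
#'
#' @param metric_vectors named list; each element a list/data.frame with
#'   components `x` and `y` (paired samples of equal length >= 2).
#' @param m number of comparisons used in the correction (default
#'   `length(metric_vectors)`).
#' @return A data.frame with columns comparison, n, t, df, p, p_corrected,
#'   degenerate.
#' @export
paired_ttest_bonferroni <- function(metric_vectors,
                                    m = length(metric_vectors)) {
  stopifnot(length(metric_vectors) >= 1L, m >= 1L)
  rows <- lapply(names(metric_vectors), function(nm) {
    mv <- metric_vectors[[nm]]
    x <- as.numeric(mv$x); y <- as.numeric(mv$y)
    if (length(x) != length(y) || length(x) < 2L)
      stop("comparison '", nm, "': paired vectors of equal length >= 2 required")
    d <- x - y
    if (stats::sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(comparison = nm, n = length(d), t = 0,
                          df = length(d) - 1L, p = 1, p_corrected = 1,
                          degenerate = FALSE))
      return(data.frame(comparison = nm, n = length(d), t = NA_real_,
                        df = length(d) - 1L, p = NA_real_,
                        p_corrected = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(comparison = nm, n = length(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               p_corrected = stats::p.adjust(tt$p.value, "bonferroni", n = m),
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}
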