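#' Preprocessing configuration
#'
#' Defaults mirror the standard T1w processing chain the package emulates:
#' a background-removing centred crop to 169 x 208 x 179 voxels followed by
#' trilinear resampling to the 128^3 network grid.
#'
#' @param crop_shape target shape of the centred crop.
#' @param model_shape shape fed to the networks (each axis must be
#'   divisible by `2^depth` of the generator used).
#' @param rescale_eps smallest admissible intensity range for
#'   [rescale_minmax()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_shape = c(169L, 208L, 179L),
                              model_shape = c(128L, 128L, 128L),
                              rescale_eps = 1e-8) {
  structure(list(crop_shape = as.integer(crop_shape),
                 model_shape = as.integer(model_shape),
                 rescale_eps = rescale_eps),
            class = "preprocess_config")
}

#' Min-max intensity rescaling
#'
#' Maps intensities affinely onto `[0, 1]`: `(x - min) / (max - min)`.
#' Idempotent on images already spanning `[0, 1]`.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param eps smallest admissible range; a (near-)constant image errors.
#' @return A [volume3d()] with `intensity_range = c(0, 1)`.
#' @export
rescale_minmax <- function(vol, eps = 1e-8) {
  vol <- as_volume3d(vol)
  lo <- min(vol$values)
  hi <- max(vol$values)
  if (hi - lo < eps)
    stop("cannot min-max rescale a (near-)constant image: range = ",
         format(hi - lo))
  volume3d((vol$values - lo) / (hi - lo), vol$voxel_size_mm,
           intensity_range = c(0, 1))
}

#' Centred crop
#'
#' Extracts the centred sub-block of the requested shape; when a margin is
#' odd the extra voxel is dropped from the high side (ties broken toward
#' the origin).
#'
#' @param vol a [volume3d()] or 3D array.
#' @param crop_shape three integers, each <= the corresponding input extent.
#' @return A [volume3d()] of shape `crop_shape`.
#' @export
crop_center <- function(vol, crop_shape) {
  vol <- as_volume3d(vol)
  d <- dim(vol$values)
  crop_shape <- as.integer(crop_shape)
  if (length(crop_shape) != 3L || any(crop_shape < 1L))
    stop("`crop_shape` must be 3 positive integers")
  if (any(crop_shape > d))
    stop("crop shape (", paste(crop_shape, collapse = "x"),
         ") exceeds input shape (", paste(d, collapse = "x"), ")")
  start <- (d - crop_shape) %/% 2L + 1L
  volume3d(vol$values[start[1L]:(start[1L] + crop_shape[1L] - 1L),
                      start[2L]:(start[2L] + crop_shape[2L] - 1L),
                      start[3L]:(start[3L] + crop_shape[3L] - 1L),
                      drop = FALSE],
           vol$voxel_size_mm, vol$intensity_range)
}

#' Trilinear resampling
#'
#' Resamples a volume to `target_shape` by trilinear interpolation on a
#' corner-aligned grid: output sample `i` (0-based) reads input coordinate
#' `i * (n_in - 1) / (n_out - 1)`, so the first and last samples of every
#' axis coincide with the input corners.  Values are convex combinations of
#' the eight surrounding voxels, hence bounded by the input min/max, and a
#' constant volume maps to the same constant.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param target_shape three positive integers.
#' @return A [volume3d()] of shape `target_shape`; voxel spacing is scaled
#'   per axis by `(n_in - 1) / (n_out - 1)`.
#' @export
resample_trilinear <- function(vol, target_shape) {
  vol <- as_volume3d(vol)
  x <- vol$values
  d <- dim(x)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("`target_shape` must be 3 positive integers")
  if (all(target_shape == d))
    return(vol)

  axis_coord <- function(n_in, n_out) {
    if (n_out == 1L) return((n_in + 1) / 2)  # single sample at the centre
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  co <- Map(axis_coord, d, target_shape)
  i0 <- vector("list", 3L); fr <- vector("list", 3L); i1 <- vector("list", 3L)
  for (a in 1:3) {
    v <- co[[a]]
    lo <- pmin(pmax(floor(v), 1), d[a] - ifelse(d[a] > 1L, 1L, 0L))
    if (d[a] == 1L) lo <- rep(1, length(v))
    i0[[a]] <- as.integer(lo)
    i1[[a]] <- as.integer(pmin(lo + 1L, d[a]))
    fr[[a]] <- v - lo
  }
  out <- array(0, dim = target_shape)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wa <- if (a == 0L) 1 - fr[[1L]] else fr[[1L]]
    wb <- if (b == 0L) 1 - fr[[2L]] else fr[[2L]]
    wc <- if (cc == 0L) 1 - fr[[3L]] else fr[[3L]]
    w <- outer(outer(wa, wb), wc)
    ia <- if (a == 0L) i0[[1L]] else i1[[1L]]
    ib <- if (b == 0L) i0[[2L]] else i1[[2L]]
    ic <- if (cc == 0L) i0[[3L]] else i1[[3L]]
    out <- out + w * x[ia, ib, ic, drop = FALSE]
  }
  sp <- vol$voxel_size_mm
  if (length(sp) == 1L) sp <- rep(sp, 3L)
  sp_out <- sp * ifelse(target_shape > 1L, (d - 1) / (target_shape - 1), 1)
  if (max(sp_out) - min(sp_out) < 1e-9) sp_out <- sp_out[1L]
  volume3d(out, sp_out, vol$intensity_range)
}

#' Quality label from the three grades
#'
#' Maps the per-characteristic grades to the image-level label: `"low"` if
#' any characteristic has grade 2, `"medium"` if any has grade 1 and none
#' has grade 2, `"good"` if all are 0.
#'
#' @param grades a [quality_grades()] object (or 3 integers in `{0,1,2}`).
#' @return `"low"`, `"medium"` or `"good"`.
#' @export
quality_label <- function(grades) {
  g <- if (inherits(grades, "quality_grades")) unlist(grades) else
    as.integer(grades)
  if (length(g) != 3L || any(is.na(g)) || !all(g %in% 0:2))
    stop("grades must be 3 integers in {0, 1, 2}")
  m <- max(g)
  c("good", "medium", "low")[m + 1L]
}

#' Split image pairs into train / test_good / test_low
#'
#' Pairs whose T1ce is low quality form `test_low` in full; of the
#' remaining (medium/good) pairs, `round(test_fraction * n)` are drawn at
#' random into `test_good` and the rest train.  The partition is exhaustive,
#' disjoint, and deterministic given `seed`.
#'
#' @param pairs a list whose elements carry `label_t1ce` (and optionally
#'   `label_t1nce`), e.g. rows of a manifest or loaded image pairs.
#' @param test_fraction fraction in (0, 1) of medium/good pairs held out.
#' @param seed integer seed.
#' @return A list with elements `train`, `test_good`, `test_low` (each a
#'   list of the input elements).
#' @export
split_dataset <- function(pairs, test_fraction = 0.10, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie strictly between 0 and 1")
  labels <- vapply(pairs, function(p) p$label_t1ce, character(1))
  if (any(!labels %in% c("good", "medium", "low")))
    stop("every pair must carry a label_t1ce in {good, medium, low}")
  idx_low <- which(labels == "low")
  idx_rest <- setdiff(seq_along(pairs), idx_low)
  n_test <- round(test_fraction * length(idx_rest))
  idx_test <- if (length(idx_rest))
    with_seed(seed, sample(idx_rest, n_test)) else integer(0)
  idx_train <- setdiff(idx_rest, idx_test)
  list(train = pairs[idx_train],
       test_good = pairs[sort(idx_test)],
       test_low = pairs[idx_low])
}
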