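#' Tissue probability maps
#'
#' Container for per-voxel GM/WM/CSF probabilities on a common grid (the
#' background class is implicit: one minus the tissue sum).
#'
#' @param gm,wm,csf numeric 3D arrays in `[0, 1]` with per-voxel sum
#'   `<= 1 + 1e-6`.
#' @param voxel_size_mm voxel edge(s) in mm.
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(gm, wm, csf, voxel_size_mm = 1) {
  stopifnot(identical(dim(gm), dim(wm)), identical(dim(gm), dim(csf)))
  s <- gm + wm + csf
  if (min(gm, wm, csf) < -1e-9 || max(s) > 1 + 1e-6)
    stop("tissue probabilities must lie in [0, 1] and sum to <= 1 per voxel")
  structure(list(probabilities = list(gm = gm, wm = wm, csf = csf),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 degenerate = FALSE),
            class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<tissue_maps> degenerate (fewer than 3 intensity modes)\n")
  } else {
    d <- dim(x$probabilities$gm)
    cat(sprintf("<tissue_maps> %s grid, spacing %s mm\n",
                paste(d, collapse = "x"),
                paste(signif(x$voxel_size_mm, 4), collapse = "x")))
  }
  invisible(x)
}

#' Simple intensity-based tissue segmentation
#'
#' A deliberately simple stand-in tissue segmenter: a three-class Gaussian
#' mixture over the masked intensities, initialized from intensity
#' quantiles and refined by expectation-maximization, with classes labelled
#' CSF / GM / WM in increasing order of their final means.  It is
#' sufficient to demonstrate how intensity shifts (such as contrast
#' enhancement) bias downstream tissue-volume estimates; it does not model
#' bias fields or spatial priors, and full segmentation frameworks can be
#' substituted by reading their probability maps from NIfTI.
#'
#' @param vol a [volume3d()] (or array) with intensities in `[0, 1]`.
#' @param mask nonempty binary brain mask on the same grid.
#' @param n_iter number of EM iterations (deterministic given the input).
#' @param init_quantiles three intensity quantiles used to initialize the
#'   class means (ascending order = CSF, GM, WM).
#' @return A [tissue_maps()] object (probabilities are zero outside the
#'   mask).  If the masked intensities show fewer than three
#'   distinguishable modes, an object with `degenerate = TRUE` and no maps
#'   is returned.
#' @export
segment_tissues_simple <- function(vol, mask, n_iter = 30L,
                                   init_quantiles = c(0.15, 0.5, 0.85)) {
  vol <- as_volume3d(vol)
  mv <- vol_values(mask) > 0
  stopifnot(identical(dim(vol$values), dim(mv)))
  if (!any(mv)) stop("mask is empty")
  v <- vol$values[mv]
  if (length(unique(round(v, 6))) < 3L)
    return(structure(list(probabilities = NULL,
                          voxel_size_mm = vol$voxel_size_mm,
                          degenerate = TRUE),
                     class = "tissue_maps"))
  mu <- as.numeric(stats::quantile(v, init_quantiles))
  sg <- rep(max(stats::sd(v) / 3, 1e-3), 3L)
  pi_k <- rep(1 / 3, 3L)
  for (it in seq_len(n_iter)) {
    dens <- vapply(1:3, function(k)
      pi_k[k] * stats::dnorm(v, mu[k], sg[k]), numeric(length(v)))
    tot <- rowSums(dens) + 1e-300
    resp <- dens / tot
    nk <- colSums(resp) + 1e-12
    mu <- colSums(resp * v) / nk
    sg <- pmax(sqrt(colSums(resp * (v - rep(mu, each = length(v)))^2) / nk),
               1e-3)
    pi_k <- nk / length(v)
  }
  ord <- order(mu)  # ascending: CSF, GM, WM
  dens <- vapply(1:3, function(k)
    pi_k[k] * stats::dnorm(v, mu[k], sg[k]), numeric(length(v)))
  resp <- dens / (rowSums(dens) + 1e-300)
  to_map <- function(k) {
    m <- array(0, dim = dim(mv))
    m[mv] <- resp[, k]
    m
  }
  tissue_maps(gm = to_map(ord[2L]), wm = to_map(ord[3L]),
              csf = to_map(ord[1L]), voxel_size_mm = vol$voxel_size_mm)
}

#' Maximum-probability binarization
#'
#' Assigns every voxel with any nonzero tissue probability to the tissue of
#' maximal probability; exact ties are broken by the fixed order
#' GM > WM > CSF.  The returned masks are disjoint and their union equals
#' the voxels with nonzero tissue probability.
#'
#' @param maps a [tissue_maps()] object.
#' @return A list of logical arrays `gm`, `wm`, `csf`.
#' @export
binarize_maxprob <- function(maps) {
  stopifnot(inherits(maps, "tissue_maps"))
  if (isTRUE(maps$degenerate)) stop("cannot binarize degenerate tissue maps")
  p <- maps$probabilities
  d <- dim(p$gm)
  m <- cbind(gm = as.vector(p$gm), wm = as.vector(p$wm),
             csf = as.vector(p$csf))
  assigned <- rowSums(m) > 0
  win <- max.col(m, ties.method = "first")   # column order = tie order
  out <- lapply(1:3, function(k) array(assigned & win == k, dim = d))
  names(out) <- c("gm", "wm", "csf")
  out
}

#' Tissue volume from a binary mask
#'
#' Multiplies the voxel count by the voxel volume; reported in cm^3.
#'
#' @param mask binary/logical 3D array.
#' @param voxel_size_mm voxel edge(s) in mm (1 or 3 values).
#' @return Volume in cm^3.
#' @export
tissue_volume <- function(mask, voxel_size_mm) {
  stopifnot(all(voxel_size_mm > 0),
            length(voxel_size_mm) %in% c(1L, 3L))
  vox_mm3 <- prod(rep(voxel_size_mm, length.out = 3L))
  sum(vol_values(mask) > 0) * vox_mm3 / 1000
}

#' Per-image tissue volumes and total intracranial volume
#'
#' @param masks list of binary masks `gm`, `wm`, `csf` (from
#'   [binarize_maxprob()]).
#' @param voxel_size_mm voxel edge(s) in mm.
#' @return A list with `volumes` (named cm^3 per tissue) and `tiv` (their
#'   sum, the total intracranial volume).
#' @export
tissue_volumes <- function(masks, voxel_size_mm) {
  v <- vapply(masks[c("gm", "wm", "csf")], tissue_volume, numeric(1),
              voxel_size_mm = voxel_size_mm)
  list(volumes = v, tiv = sum(v))
}

#' Absolute and signed volume difference
#'
#' The (absolute) tissue-volume difference between a reference image I and
#' a comparison image J, expressed as a fraction of the reference total
#' intracranial volume and rescaled by a common average TIV so the result
#' reads in cm^3: `AVD = |V_I - V_J| / TIV_I * tiv_bar` and
#' `VD = (V_I - V_J) / TIV_I * tiv_bar`.  `avd(...) == abs(vd(...))` by
#' construction; negative VD means the comparison image over-estimates the
#' volume.
#'
#' @param v_i,v_j tissue volume (cm^3) in the reference and comparison
#'   image.
#' @param tiv_i total intracranial volume of the reference image (> 0).
#' @param tiv_bar average TIV used for rescaling (a constant; it does not
#'   affect comparisons).
#' @return Volume difference in cm^3 (AVD >= 0; VD signed).
#' @export
avd <- function(v_i, v_j, tiv_i, tiv_bar) {
  abs(vd(v_i, v_j, tiv_i, tiv_bar))
}

#' @rdname avd
#' @export
vd <- function(v_i, v_j, tiv_i, tiv_bar) {
  if (any(tiv_i <= 0)) stop("`tiv_i` must be > 0")
  (v_i - v_j) / tiv_i * tiv_bar
}

#' Dice overlap of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`.  Returns `NA` (degenerate) when both
#' masks are empty.
#'
#' @param a,b binary/logical arrays on one grid.
#' @return Dice score in `[0, 1]`, or `NA` if both masks are empty.
#' @export
dice <- function(a, b) {
  av <- vol_values(a) > 0; bv <- vol_values(b) > 0
  if (!identical(dim(av), dim(bv))) stop("masks must share one grid")
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(av & bv) / (na + nb)
}

#' Resample a synthetic volume back to a reference grid
#'
#' Trilinear resampling to the reference shape so that real and synthetic
#' images share one grid before segmentation; delegates to
#' [resample_trilinear()].
#'
#' @inheritParams resample_trilinear
#' @return A [volume3d()] of shape `target_shape`.
#' @export
resample_back <- function(vol, target_shape) {
  resample_trilinear(vol, target_shape)
}

#' Compare two segmentations of one subject
#'
#' Binarizes both sets of probability maps, computes per-tissue volumes,
#' and reports AVD, VD (normalized by the reference TIV, rescaled by
#' `tiv_bar`) and Dice per tissue.
#'
#' @param ref_maps,cmp_maps [tissue_maps()] of the reference (real T1nce)
#'   and comparison (T1ce or synthetic T1nce) image.
#' @param tiv_bar average reference TIV used for rescaling; defaults to the
#'   reference image's own TIV.
#' @return A data.frame with one row per tissue: `tissue`, `v_ref`,
#'   `v_cmp`, `avd`, `vd`, `dice`, `tiv_ref`, `tiv_bar`.
#' @export
compare_segmentations <- function(ref_maps, cmp_maps, tiv_bar = NULL) {
  ref_bin <- binarize_maxprob(ref_maps)
  cmp_bin <- binarize_maxprob(cmp_maps)
  tv_ref <- tissue_volumes(ref_bin, ref_maps$voxel_size_mm)
  tv_cmp <- tissue_volumes(cmp_bin, cmp_maps$voxel_size_mm)
  tb <- tiv_bar %||% tv_ref$tiv
  data.frame(
    tissue = c("gm", "wm", "csf"),
    v_ref = unname(tv_ref$volumes),
    v_cmp = unname(tv_cmp$volumes),
    avd = avd(unname(tv_ref$volumes), unname(tv_cmp$volumes), tv_ref$tiv, tb),
    vd = vd(unname(tv_ref$volumes), unname(tv_cmp$volumes), tv_ref$tiv, tb),
    dice = vapply(c("gm", "wm", "csf"),
                  function(t) dice(ref_bin[[t]], cmp_bin[[t]]), numeric(1)),
    tiv_ref = tv_ref$tiv, tiv_bar = tb, row.names = NULL)
}
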