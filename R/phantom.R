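#' Quality grades for one image
#'
#' Three-level grades (0, 1, 2) for the three quality characteristics used
#' to rate clinical T1-weighted images: contrast, motion and noise.  Grade 0
#' means good contrast / no motion / no noise, grade 1 medium contrast /
#' some motion / some noise, grade 2 bad contrast / severe motion / severe
#' noise.  See [quality_label()] for the mapping to good/medium/low labels.
#'
#' @param contrast,motion,noise integer grade in `{0, 1, 2}`.
#' @return An object of class `quality_grades`.
#' @export
quality_grades <- function(contrast = 0L, motion = 0L, noise = 0L) {
  g <- c(contrast = as.integer(contrast), motion = as.integer(motion),
         noise = as.integer(noise))
  if (any(is.na(g)) || !all(g %in% 0:2))
    stop("quality grades must be integers in {0, 1, 2}")
  structure(as.list(g), class = "quality_grades")
}

#' @export
print.quality_grades <- function(x, ...) {
  cat(sprintf("<quality_grades> contrast=%d motion=%d noise=%d (%s)\n",
              x$contrast, x$motion, x$noise, quality_label(x)))
  invisible(x)
}

#' Parameters of the paired brain phantom
#'
#' Settings of the synthetic paired-volume generator.  The phantom emulates
#' the statistical structure of a paired clinical T1ce/T1nce data set:
#' nested tissue compartments (WM core, GM ribbon, CSF shell and
#' ventricles), an enhancing compartment (meningeal/vascular shell patches
#' plus random vessel-like tubes) brightened by `delta` on the T1ce, a
#' GM-intensity shift `contrast_shift` emulating the altered tissue
#' contrast under gadolinium, and additive Gaussian intensity noise.
#'
#' @param grid_shape three positive integers (each >= 8), voxels per axis.
#' @param voxel_size_mm positive voxel edge in mm.  The default 6 mm on a
#'   32^3 grid spans a head-sized 19.2 cm field of view.
#' @param tissue_means named intensities in `[0, 1]` for `wm`, `gm`, `csf`
#'   and `background`.
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   shared by the two volumes of a pair (>= 0).
#' @param delta additive enhancement intensity in the enhancing
#'   compartment (>= 0).
#' @param contrast_shift signed intensity added to GM under enhancement.
#' @param seed integer seed; phantoms are bit-reproducible given the seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(32L, 32L, 32L),
                           voxel_size_mm = 6,
                           tissue_means = c(wm = 0.75, gm = 0.55,
                                            csf = 0.20, background = 0),
                           noise_sigma = 0.01,
                           delta = 0.30,
                           contrast_shift = 0.05,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("`grid_shape` must be 3 integers, each >= 8")
  stopifnot(length(voxel_size_mm) == 1L, voxel_size_mm > 0)
  need <- c("wm", "gm", "csf", "background")
  if (!all(need %in% names(tissue_means)))
    stop("`tissue_means` must name wm, gm, csf and background")
  if (any(tissue_means < 0 | tissue_means > 1))
    stop("tissue means must lie in [0, 1]")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (delta < 0) stop("`delta` must be >= 0")
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm,
                 tissue_means = tissue_means[need],
                 noise_sigma = noise_sigma,
                 delta = delta,
                 contrast_shift = contrast_shift,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Squared ellipsoidal radius field for per-axis normalized coordinates.
ellipsoid_r2 <- function(coords, center, axes) {
  ru <- ((coords[[1L]] - center[1L]) / axes[1L])^2
  rh <- ((coords[[2L]] - center[2L]) / axes[2L])^2
  rw <- ((coords[[3L]] - center[3L]) / axes[3L])^2
  outer(outer(ru, rh, "+"), rw, "+")
}

#' Generate one paired brain phantom
#'
#' Builds a synthetic subject: a T1nce volume made of nested ellipsoidal
#' tissue compartments with additive Gaussian noise, the corresponding T1ce
#' obtained with [apply_enhancement()], ground-truth tissue probability
#' maps, the brain mask, and the recorded enhancing compartment.  If grades
#' other than (0,0,0) are supplied the respective volume is additionally
#' passed through [degrade_quality()].  Output is deterministic given
#' `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @param grades_t1ce,grades_t1nce [quality_grades()] for each volume.
#' @param subject_id identifier stored with the sample.
#' @return An object of class `phantom_sample` with fields `t1nce`, `t1ce`
#'   ([volume3d()]), `brain_mask`, `tissue_truth`, `enhancing`,
#'   `grades_t1ce`, `grades_t1nce`, `subject_id`.
#' @export
make_phantom <- function(params = phantom_params(),
                         grades_t1ce = quality_grades(),
                         grades_t1nce = quality_grades(),
                         subject_id = "sub-001") {
  stopifnot(inherits(params, "phantom_params"),
            inherits(grades_t1ce, "quality_grades"),
            inherits(grades_t1nce, "quality_grades"))
  gs <- params$grid_shape
  tm <- params$tissue_means

  geom <- with_seed(params$seed, {
    coords <- lapply(gs, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
    center <- stats::runif(3L, -0.04, 0.04)
    outer_axes <- c(0.86, 0.90, 0.84) * (1 + stats::runif(3L, -0.05, 0.05))
    r2_out <- ellipsoid_r2(coords, center, outer_axes)
    r2_gm <- ellipsoid_r2(coords, center, outer_axes * 0.88)
    r2_wm <- ellipsoid_r2(coords, center, outer_axes * 0.72)
    vent1 <- ellipsoid_r2(coords, center + c(0.16, 0.05, 0),
                          c(0.10, 0.24, 0.14))
    vent2 <- ellipsoid_r2(coords, center + c(-0.16, 0.05, 0),
                          c(0.10, 0.24, 0.14))

    brain <- r2_out <= 1
    gm_all <- r2_gm <= 1
    wm_all <- r2_wm <= 1
    vent <- (vent1 <= 1 | vent2 <= 1) & wm_all

    wm <- wm_all & !vent
    gm <- gm_all & !wm_all
    csf <- (brain & !gm_all) | vent
    if (!any(wm) || !any(gm) || !any(csf))
      stop("grid too small to fit nested tissue compartments")

    # Enhancing compartment: angular patches of the outer (meningeal) shell
    # plus vessel-like tubes through the brain interior.
    X <- array(rep(coords[[1L]] - center[1L], times = gs[2L] * gs[3L]), gs)
    Y <- array(rep(rep(coords[[2L]] - center[2L], each = gs[1L]),
                   times = gs[3L]), gs)
    Z <- array(rep(coords[[3L]] - center[3L], each = gs[1L] * gs[2L]), gs)
    rad <- sqrt(X^2 + Y^2 + Z^2)
    rad[rad < 1e-9] <- 1e-9
    shell <- brain & r2_out >= 0.80
    patches <- array(FALSE, gs)
    for (k in seq_len(6L)) {
      d <- stats::rnorm(3L)
      d <- d / sqrt(sum(d^2))
      patches <- patches | ((X * d[1L] + Y * d[2L] + Z * d[3L]) / rad > 0.85)
    }
    tubes <- array(FALSE, gs)
    for (k in seq_len(3L)) {
      p <- stats::runif(3L, -0.45, 0.45)
      q <- stats::runif(3L, -0.45, 0.45)
      v <- q - p
      vv <- max(sum(v^2), 1e-9)
      tt <- ((X - p[1L]) * v[1L] + (Y - p[2L]) * v[2L] + (Z - p[3L]) * v[3L]) / vv
      tt <- pmin(pmax(tt, 0), 1)
      d2 <- (X - p[1L] - tt * v[1L])^2 + (Y - p[2L] - tt * v[2L])^2 +
        (Z - p[3L] - tt * v[3L])^2
      tubes <- tubes | (d2 <= 0.06^2)
    }
    enhancing <- ((shell & patches) | tubes) & brain

    base <- array(tm[["background"]], gs)
    base[csf] <- tm[["csf"]]
    base[gm] <- tm[["gm"]]
    base[wm] <- tm[["wm"]]
    if (params$noise_sigma > 0)
      base <- clip01(base + array(stats::rnorm(prod(gs), 0, params$noise_sigma), gs))
    list(brain = brain, gm = gm, wm = wm, csf = csf,
         enhancing = enhancing, t1nce = base)
  })

  maps <- structure(
    list(probabilities = list(gm = geom$gm + 0, wm = geom$wm + 0,
                              csf = geom$csf + 0),
         voxel_size_mm = params$voxel_size_mm),
    class = "tissue_maps")

  sample <- structure(
    list(t1nce = volume3d(geom$t1nce, params$voxel_size_mm),
         t1ce = NULL,
         brain_mask = geom$brain,
         tissue_truth = maps,
         enhancing = geom$enhancing,
         grades_t1ce = grades_t1ce,
         grades_t1nce = grades_t1nce,
         subject_id = subject_id,
         params = params),
    class = "phantom_sample")

  sample$t1ce <- apply_enhancement(sample, params$delta, params$contrast_shift)

  if (max(unlist(grades_t1nce)) > 0L)
    sample$t1nce <- degrade_quality(sample$t1nce, grades_t1nce,
                                    seed = derive_seed(params$seed, 11L))
  if (max(unlist(grades_t1ce)) > 0L)
    sample$t1ce <- degrade_quality(sample$t1ce, grades_t1ce,
                                   seed = derive_seed(params$seed, 12L))
  sample
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s: grid %s, %d brain voxels, %d enhancing\n",
              x$subject_id, paste(dim(x$t1nce$values), collapse = "x"),
              sum(x$brain_mask), sum(x$enhancing)))
  invisible(x)
}

#' Apply the gadolinium-enhancement transform
#'
#' Produces the contrast-enhanced member of a phantom pair from the
#' non-enhanced one: `t1ce = clip01(t1nce + delta * enhancing +
#' contrast_shift * GM)`.  Voxels outside the enhancing and GM compartments
#' are unchanged.
#'
#' @param sample a `phantom_sample` from [make_phantom()].
#' @param delta additive intensity in the enhancing compartment (>= 0).
#' @param contrast_shift signed intensity added inside gray matter.
#' @return A [volume3d()] with the enhanced intensities.
#' @export
apply_enhancement <- function(sample, delta = sample$params$delta,
                              contrast_shift = sample$params$contrast_shift) {
  stopifnot(inherits(sample, "phantom_sample"), delta >= 0)
  x <- sample$t1nce$values
  gm <- sample$tissue_truth$probabilities$gm > 0.5
  y <- x + delta * sample$enhancing + contrast_shift * gm
  if (delta > 0 || contrast_shift != 0) y <- clip01(y)
  volume3d(y, sample$t1nce$voxel_size_mm)
}

#' Degradation operator constants
#'
#' The quality grades are defined semantically (good/medium/bad contrast,
#' no/some/severe motion and noise); this config fixes the numeric strength
#' of the operator realizing each grade: contrast compression factors
#' towards the volume mean (`c1`, `c2`), directional Gaussian blur widths in
#' voxels (`blur_sd1`, `blur_sd2`) and additive noise standard deviations
#' (`noise_sd1`, `noise_sd2`).  Grade 0 always leaves the aspect untouched.
#'
#' @param c1,c2 contrast compression in `[0, 1)` for grades 1 and 2.
#' @param blur_sd1,blur_sd2 motion blur standard deviations (voxels).
#' @param noise_sd1,noise_sd2 noise standard deviations (intensity units).
#' @return A list of class `degrade_config`.
#' @export
degrade_config <- function(c1 = 0.3, c2 = 0.6,
                           blur_sd1 = 0.6, blur_sd2 = 1.2,
                           noise_sd1 = 0.02, noise_sd2 = 0.05) {
  structure(list(contrast = c(0, c1, c2),
                 blur_sd = c(0, blur_sd1, blur_sd2),
                 noise_sd = c(0, noise_sd1, noise_sd2)),
            class = "degrade_config")
}

# Edge-replicating shift of a 3D array by k voxels along one axis.
shift_axis <- function(x, k, axis) {
  n <- dim(x)[axis]
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

# 1D Gaussian blur along `axis` with edge replication.
blur_axis <- function(x, sd, axis) {
  r <- max(1L, ceiling(2.5 * sd))
  w <- stats::dnorm(seq(-r, r), sd = sd)
  w <- w / sum(w)
  y <- array(0, dim = dim(x))
  for (j in seq_along(w)) y <- y + w[j] * shift_axis(x, j - r - 1L, axis)
  y
}

#' Degrade a volume according to quality grades
#'
#' Realizes the three graded degradation axes on an image: the contrast
#' grade compresses intensities towards the volume mean, the motion grade
#' applies a directional (single random axis) Gaussian blur, and the noise
#' grade adds Gaussian noise.  Grades (0,0,0) return the input unchanged,
#' bit for bit.  Deterministic given `seed`.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param grades a [quality_grades()] object.
#' @param seed integer seed for the blur direction and the noise draw.
#' @param config a [degrade_config()].
#' @return A [volume3d()].
#' @export
degrade_quality <- function(vol, grades, seed = 1L, config = degrade_config()) {
  stopifnot(inherits(grades, "quality_grades"),
            inherits(config, "degrade_config"))
  vol <- as_volume3d(vol)
  if (grades$contrast == 0L && grades$motion == 0L && grades$noise == 0L)
    return(vol)
  x <- vol$values
  with_seed(seed, {
    if (grades$contrast > 0L) {
      cg <- config$contrast[grades$contrast + 1L]
      m <- mean(x)
      x <- m + (1 - cg) * (x - m)
    }
    if (grades$motion > 0L) {
      axis <- sample.int(3L, 1L)
      x <- blur_axis(x, config$blur_sd[grades$motion + 1L], axis)
    }
    if (grades$noise > 0L) {
      x <- x + array(stats::rnorm(length(x), 0,
                                  config$noise_sd[grades$noise + 1L]), dim(x))
    }
    volume3d(clip01(x), vol$voxel_size_mm)
  })
}

# Sample per-image quality grades for a simulated subject.  T1nce images are
# always of medium or good quality (the pairing rule of the data set);
# `force_low` makes the T1ce low quality by forcing at least one grade-2
# characteristic.
sample_grades <- function(force_low = FALSE) {
  if (force_low) {
    g <- sample(0:2, 3L, replace = TRUE, prob = c(0.4, 0.3, 0.3))
    if (!any(g == 2L)) g[sample.int(3L, 1L)] <- 2L
  } else {
    g <- sample(0:1, 3L, replace = TRUE, prob = c(0.6, 0.4))
  }
  quality_grades(g[1L], g[2L], g[3L])
}

#' Simulate a paired phantom data set on disk
#'
#' Generates `n_pairs` paired phantoms and writes them as a BIDS-like tree:
#' `sub-XXX/ses-M000/anat/sub-XXX_ses-M000[_ce-gadolinium]_T1w.nii.gz` with
#' JSON sidecars carrying the quality grades and ground-truth paths, ground
#' truth (brain mask and GM/WM/CSF probability maps) under
#' `derivatives/phantom/`, and a dataset-level `manifest.tsv`.
#'
#' Exactly `n_low_t1ce` subjects receive a low-quality T1ce (at least one
#' grade-2 characteristic); every other image draws its grades in {0, 1},
#' and T1nce images are always of medium or good quality, mirroring the
#' pairing rule of the clinical data set the phantom emulates.
#'
#' @param out_dir output directory (created if needed).
#' @param n_pairs number of subjects.
#' @param params base [phantom_params()]; each subject uses a derived seed.
#' @param n_low_t1ce number of subjects with a low-quality T1ce.
#' @param seed master seed for subject geometry and grade sampling.
#' @return The manifest as a data.frame, invisibly.
#' @export
simulate_dataset <- function(out_dir, n_pairs = 32L,
                             params = phantom_params(),
                             n_low_t1ce = 4L,
                             seed = params$seed) {
  stopifnot(n_pairs >= 1L, n_low_t1ce >= 0L, n_low_t1ce <= n_pairs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  low_set <- with_seed(derive_seed(seed, 1L),
                       sample.int(n_pairs, n_low_t1ce))
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    sid <- sprintf("sub-%03d", i)
    grades <- with_seed(derive_seed(seed, 100L + i), list(
      t1ce = sample_grades(force_low = i %in% low_set),
      t1nce = sample_grades(force_low = FALSE)))
    p_i <- params
    p_i$seed <- derive_seed(seed, 200L + i)
    smp <- make_phantom(p_i, grades_t1ce = grades$t1ce,
                        grades_t1nce = grades$t1nce, subject_id = sid)

    anat <- file.path(out_dir, sid, "ses-M000", "anat")
    deriv <- file.path(out_dir, "derivatives", "phantom", sid)
    p_t1ce <- file.path(anat, sprintf("%s_ses-M000_ce-gadolinium_T1w.nii.gz", sid))
    p_t1nce <- file.path(anat, sprintf("%s_ses-M000_T1w.nii.gz", sid))
    p_mask <- file.path(deriv, sprintf("%s_brainmask.nii.gz", sid))
    write_volume(smp$t1ce, p_t1ce)
    write_volume(smp$t1nce, p_t1nce)
    write_volume(volume3d(smp$brain_mask + 0, params$voxel_size_mm), p_mask)
    truth_paths <- list(brain_mask = p_mask)
    for (t in c("gm", "wm", "csf")) {
      pt <- file.path(deriv, sprintf("%s_probmap-%s.nii.gz", sid, t))
      write_volume(volume3d(smp$tissue_truth$probabilities[[t]],
                            params$voxel_size_mm), pt)
      truth_paths[[t]] <- pt
    }
    for (side in c("t1ce", "t1nce")) {
      g <- grades[[side]]
      sidecar <- list(
        ContrastBolusIngredient = if (side == "t1ce") "GADOLINIUM" else NULL,
        QualityGrades = list(contrast = g$contrast, motion = g$motion,
                             noise = g$noise),
        QualityLabel = quality_label(g),
        GroundTruth = truth_paths)
      jp <- sub("\\.nii\\.gz$", ".json",
                if (side == "t1ce") p_t1ce else p_t1nce)
      writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE,
                                  null = "null"), jp)
    }
    rows[[i]] <- data.frame(
      subject = sid, session = "ses-M000",
      path_t1ce = p_t1ce, path_t1nce = p_t1nce,
      t1ce_contrast = grades$t1ce$contrast, t1ce_motion = grades$t1ce$motion,
      t1ce_noise = grades$t1ce$noise,
      t1nce_contrast = grades$t1nce$contrast,
      t1nce_motion = grades$t1nce$motion, t1nce_noise = grades$t1nce$noise,
      label_t1ce = quality_label(grades$t1ce),
      label_t1nce = quality_label(grades$t1nce),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
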