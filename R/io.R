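#' Build a dataset manifest from a BIDS-like tree
#'
#' Scans `sub-*/ses-*/anat` for T1-weighted images, pairing the
#' contrast-enhanced image (filename entity `ce-gadolinium`) with the
#' non-enhanced image of the same subject and session.  Sessions lacking
#' either member are excluded (only complete pairs enter the data set).
#' Quality grades and labels are read from the JSON sidecars when present.
#'
#' @param bids_dir root of the BIDS-like tree (as written by
#'   [simulate_dataset()]).
#' @return A data.frame with one row per complete subject-session pair:
#'   subject, session, paths, grades, quality labels.
#' @export
build_manifest <- function(bids_dir) {
  stopifnot(dir.exists(bids_dir))
  files <- list.files(bids_dir, pattern = "_T1w\\.nii(\\.gz)?$",
                      recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("derivatives", files, fixed = TRUE)]
  if (length(files) == 0L)
    return(data.frame(subject = character(0), session = character(0),
                      path_t1ce = character(0), path_t1nce = character(0)))
  bn <- basename(files)
  subject <- sub("^(sub-[^_]+)_.*$", "\\1", bn)
  session <- sub("^sub-[^_]+_(ses-[^_]+)_.*$", "\\1", bn)
  is_ce <- grepl("_ce-gadolinium_", bn, fixed = TRUE)
  key <- paste(subject, session)

  rows <- lapply(sort(unique(key)), function(k) {
    sel <- key == k
    ce <- files[sel & is_ce]
    nce <- files[sel & !is_ce]
    if (length(ce) > 1L || length(nce) > 1L)
      stop("duplicate T1w entities for ", k)
    if (length(ce) != 1L || length(nce) != 1L) return(NULL)  # incomplete
    side <- function(path, default_label = "good") {
      jp <- sub("\\.nii(\\.gz)?$", ".json", path)
      if (file.exists(jp)) {
        js <- jsonlite::fromJSON(jp)
        g <- js$QualityGrades
        list(grades = c(g$contrast, g$motion, g$noise),
             label = js$QualityLabel %||%
               quality_label(c(g$contrast, g$motion, g$noise)),
             truth = js$GroundTruth)
      } else list(grades = c(0L, 0L, 0L), label = default_label, truth = NULL)
    }
    ce_i <- side(ce); nce_i <- side(nce)
    data.frame(subject = strsplit(k, " ")[[1L]][1L],
               session = strsplit(k, " ")[[1L]][2L],
               path_t1ce = ce, path_t1nce = nce,
               t1ce_contrast = ce_i$grades[1L], t1ce_motion = ce_i$grades[2L],
               t1ce_noise = ce_i$grades[3L],
               t1nce_contrast = nce_i$grades[1L],
               t1nce_motion = nce_i$grades[2L],
               t1nce_noise = nce_i$grades[3L],
               label_t1ce = ce_i$label, label_t1nce = nce_i$label,
               path_brain_mask = ce_i$truth$brain_mask %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(subject = character(0), session = character(0),
                      path_t1ce = character(0), path_t1nce = character(0)))
  rownames(out) <- NULL
  out
}

#' Load image pairs listed in a manifest
#'
#' @param manifest a manifest data.frame from [build_manifest()].
#' @return A list of pairs: each has `t1ce`, `t1nce` ([volume3d()]),
#'   `brain_mask` (logical array or `NULL`), `label_t1ce`, `label_t1nce`,
#'   `subject_id`.
#' @export
load_pairs <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    mask <- if (!is.na(r$path_brain_mask) && file.exists(r$path_brain_mask))
      read_volume(r$path_brain_mask)$values > 0 else NULL
    list(t1ce = read_volume(r$path_t1ce),
         t1nce = read_volume(r$path_t1nce),
         brain_mask = mask,
         label_t1ce = r$label_t1ce, label_t1nce = r$label_t1nce,
         subject_id = r$subject)
  })
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    phantom = list(n_pairs = 32L, grid = 32L, voxel_size_mm = 6,
                   noise_sigma = 0.01, delta = 0.30, contrast_shift = 0.05,
                   n_low_t1ce = 4L),
    preprocess = list(model_shape = NULL, test_fraction = 0.29),
    generator = list(variant = "att", depth = 4L, base_channels = 6L),
    train = list(mode = "generator", epochs = 30L, lr = 1e-3,
                 batch_size = 2L, loss_mode = "least_squares",
                 l1_weight = 1, pretrain_epochs = 2L, cgan_epochs = 3L,
                 disc_base_channels = 8L),
    evaluation = list(ssim_window = 7L, seg_iters = 30L)
  )
}

merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1L) "s" else "", ": ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "$"))
    else user[[k]]
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds the nested configuration of the end-to-end pipeline, validating
#' every key against the documented defaults (unknown keys are rejected).
#' Top-level sections: `phantom` (data generation), `preprocess` (model
#' grid and split), `generator`, `train` and `evaluation`; plus the master
#' `seed` (all stage seeds are derived from it by fixed offsets) and
#' `out_dir`.
#'
#' @param ... named overrides, e.g. `seed = 7`, `train = list(epochs = 5)`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1L]]))
    user <- user[[1L]]
  cfg <- merge_config(user, default_run_config())
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full translation pipeline
#'
#' Chains simulate -> preprocess -> split -> train -> translate ->
#' evaluate: generates a paired phantom data set on disk, loads and
#' rescales it, splits it into train / test_good / test_low, trains the
#' configured generator (optionally followed by adversarial fine-tuning),
#' translates the test T1ce volumes, and evaluates brain-masked image
#' similarity (MAE/PSNR/SSIM, paired t-tests with Bonferroni correction)
#' and tissue-volume fidelity (AVD/VD/Dice against the stand-in segmenter).
#' Per-pair tables and summary CSVs are written to `cfg$out_dir`, along
#' with a JSON summary stamped with the seed and a configuration hash.
#'
#' @param cfg a [run_config()]; `out_dir` must be set.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `similarity` and `segmentation` per-pair
#'   data.frames, `tests` (t-test tables), `summary` (named numbers),
#'   `history`, `checkpoint` and `paths`.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out_dir)) stop("cfg$out_dir must be set")
  t0 <- Sys.time()
  log <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(unclass(cfg))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log("[simulate] %d phantom pairs (grid %d^3, seed %d, config %s)",
      cfg$phantom$n_pairs, cfg$phantom$grid, cfg$seed, hash)

  pp <- phantom_params(grid_shape = rep(cfg$phantom$grid, 3L),
                       voxel_size_mm = cfg$phantom$voxel_size_mm,
                       noise_sigma = cfg$phantom$noise_sigma,
                       delta = cfg$phantom$delta,
                       contrast_shift = cfg$phantom$contrast_shift,
                       seed = derive_seed(cfg$seed, 1L))
  bids_dir <- file.path(cfg$out_dir, "bids")
  simulate_dataset(bids_dir, n_pairs = cfg$phantom$n_pairs, params = pp,
                   n_low_t1ce = cfg$phantom$n_low_t1ce,
                   seed = derive_seed(cfg$seed, 2L))
  manifest <- build_manifest(bids_dir)
  pairs <- load_pairs(manifest)

  log("[preprocess] rescaling %d pairs", length(pairs))
  pairs <- lapply(pairs, function(p) {
    p$t1ce <- rescale_minmax(p$t1ce)
    p$t1nce <- rescale_minmax(p$t1nce)
    ms <- cfg$preprocess$model_shape
    if (!is.null(ms) && !all(dim(p$t1ce$values) == ms)) {
      p$t1ce <- resample_trilinear(p$t1ce, ms)
      p$t1nce <- resample_trilinear(p$t1nce, ms)
    }
    p
  })

  split <- split_dataset(pairs, test_fraction = cfg$preprocess$test_fraction,
                         seed = derive_seed(cfg$seed, 3L))
  log("[split] train=%d test_good=%d test_low=%d",
      length(split$train), length(split$test_good), length(split$test_low))
  if (length(split$train) == 0L) stop("empty training split")

  gshape <- dim(split$train[[1L]]$t1ce$values)
  gen_cfg <- generator_config(variant = cfg$generator$variant,
                              input_shape = gshape,
                              depth = cfg$generator$depth,
                              base_channels = cfg$generator$base_channels,
                              seed = derive_seed(cfg$seed, 4L))
  tr_cfg <- train_config(epochs = cfg$train$epochs,
                         batch_size_generator_only = cfg$train$batch_size,
                         lr = cfg$train$lr,
                         loss_mode = cfg$train$loss_mode,
                         l1_weight = cfg$train$l1_weight,
                         seed = derive_seed(cfg$seed, 5L))
  log("[train] %s generator, %d epochs, %d pairs",
      cfg$generator$variant, cfg$train$epochs, length(split$train))
  run <- train_generator_only(split$train, gen_cfg, tr_cfg)
  ckpt <- run$checkpoint
  history <- run$history

  if (cfg$train$mode == "cgan") {
    log("[train] adversarial fine-tuning (%d pretrain + %d cGAN epochs)",
        cfg$train$pretrain_epochs, cfg$train$cgan_epochs)
    dcfg <- discriminator_config(
      patch_size = as.integer(gshape[1L] %/% 2L),
      base_channels = cfg$train$disc_base_channels,
      seed = derive_seed(cfg$seed, 6L))
    pre <- pretrain_discriminator(
      split$train, ckpt, dcfg,
      train_config(epochs = cfg$train$pretrain_epochs, lr = cfg$train$lr,
                   seed = derive_seed(cfg$seed, 7L)))
    cg <- train_cgan(split$train, ckpt, pre$checkpoint,
                     train_config(epochs = cfg$train$cgan_epochs,
                                  lr = cfg$train$lr,
                                  loss_mode = cfg$train$loss_mode,
                                  l1_weight = cfg$train$l1_weight,
                                  seed = derive_seed(cfg$seed, 8L)))
    ckpt <- cg$checkpoint
    history <- list(generator = history, cgan = cg$history)
  }

  model <- restore_model(ckpt)
  log("[translate + evaluate] %d test pairs",
      length(split$test_good) + length(split$test_low))
  sim_rows <- list()
  seg_rows <- list()
  seg_cache <- list()
  for (set_name in c("test_good", "test_low")) {
    for (p in split[[set_name]]) {
      synth <- translate_volume(model, p$t1ce)
      msk <- p$brain_mask %||% (p$t1nce$values > 0.05)
      w <- cfg$evaluation$ssim_window
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        test_set = set_name, subject = p$subject_id,
        comparison = c("t1nce_vs_t1ce", "t1nce_vs_synthetic"),
        mae_percent = c(mae(p$t1nce, p$t1ce, msk),
                        mae(p$t1nce, synth, msk)),
        psnr_db = c(psnr(p$t1nce, p$t1ce, msk), psnr(p$t1nce, synth, msk)),
        ssim = c(ssim(p$t1nce, p$t1ce, msk, window = w),
                 ssim(p$t1nce, synth, msk, window = w)),
        mask_voxels = sum(msk))
      ref <- segment_tissues_simple(p$t1nce, msk,
                                    n_iter = cfg$evaluation$seg_iters)
      seg_cache[[length(seg_cache) + 1L]] <- list(
        test_set = set_name, subject = p$subject_id, ref = ref,
        t1ce = segment_tissues_simple(p$t1ce, msk,
                                      n_iter = cfg$evaluation$seg_iters),
        synthetic = segment_tissues_simple(synth, msk,
                                           n_iter = cfg$evaluation$seg_iters))
    }
  }
  # Average reference TIV across the two test sets (the common rescaler).
  ref_tivs <- vapply(seg_cache, function(s) {
    if (isTRUE(s$ref$degenerate)) return(NA_real_)
    tissue_volumes(binarize_maxprob(s$ref), s$ref$voxel_size_mm)$tiv
  }, numeric(1))
  tiv_bar <- mean(ref_tivs, na.rm = TRUE)
  for (s in seg_cache) {
    for (cmp in c("t1ce", "synthetic")) {
      if (isTRUE(s$ref$degenerate) || isTRUE(s[[cmp]]$degenerate)) {
        warning("degenerate segmentation for ", s$subject, " (", cmp,
                "); recorded as missing")
        tab <- data.frame(tissue = c("gm", "wm", "csf"), v_ref = NA_real_,
                          v_cmp = NA_real_, avd = NA_real_, vd = NA_real_,
                          dice = NA_real_, tiv_ref = NA_real_,
                          tiv_bar = tiv_bar)
      } else {
        tab <- compare_segmentations(s$ref, s[[cmp]], tiv_bar = tiv_bar)
      }
      tab$test_set <- s$test_set
      tab$subject <- s$subject
      tab$comparison <- paste0("t1nce_vs_", cmp)
      seg_rows[[length(seg_rows) + 1L]] <- tab
    }
  }
  similarity <- do.call(rbind, sim_rows)
  segmentation <- do.call(rbind, seg_rows)

  # Paired t-tests: baseline vs synthetic per metric (similarity) and per
  # tissue (AVD), Bonferroni-corrected within each family.
  tests <- list()
  base <- similarity[similarity$comparison == "t1nce_vs_t1ce", ]
  syn <- similarity[similarity$comparison == "t1nce_vs_synthetic", ]
  if (nrow(base) >= 2L) {
    mv <- list(mae = list(x = base$mae_percent, y = syn$mae_percent),
               psnr = list(x = base$psnr_db, y = syn$psnr_db),
               ssim = list(x = base$ssim, y = syn$ssim))
    tests$similarity <- paired_ttest_bonferroni(mv)
  }
  aw <- function(tis, cmp)
    segmentation$avd[segmentation$tissue == tis &
                       segmentation$comparison == cmp]
  if (nrow(segmentation) >= 12L) {
    mv <- lapply(stats::setNames(c("gm", "wm", "csf"), c("gm", "wm", "csf")),
                 function(t) {
                   x <- aw(t, "t1nce_vs_t1ce")
                   y <- aw(t, "t1nce_vs_synthetic")
                   ok <- is.finite(x) & is.finite(y)
                   list(x = x[ok], y = y[ok])
                 })
    if (all(vapply(mv, function(z) length(z$x) >= 2L, logical(1))))
      tests$avd <- paired_ttest_bonferroni(mv)
  }

  summary_nums <- c(
    mae_t1ce = mean(base$mae_percent), mae_synthetic = mean(syn$mae_percent),
    psnr_t1ce = mean(base$psnr_db[is.finite(base$psnr_db)]),
    psnr_synthetic = mean(syn$psnr_db[is.finite(syn$psnr_db)]),
    ssim_t1ce = mean(base$ssim), ssim_synthetic = mean(syn$ssim),
    avd_gm_t1ce = mean(aw("gm", "t1nce_vs_t1ce"), na.rm = TRUE),
    avd_gm_synthetic = mean(aw("gm", "t1nce_vs_synthetic"), na.rm = TRUE),
    avd_wm_t1ce = mean(aw("wm", "t1nce_vs_t1ce"), na.rm = TRUE),
    avd_wm_synthetic = mean(aw("wm", "t1nce_vs_synthetic"), na.rm = TRUE),
    avd_csf_t1ce = mean(aw("csf", "t1nce_vs_t1ce"), na.rm = TRUE),
    avd_csf_synthetic = mean(aw("csf", "t1nce_vs_synthetic"), na.rm = TRUE),
    tiv_bar = tiv_bar,
    n_train = length(split$train), n_test_good = length(split$test_good),
    n_test_low = length(split$test_low))

  paths <- list(
    similarity = file.path(cfg$out_dir, "similarity.csv"),
    segmentation = file.path(cfg$out_dir, "segmentation.csv"),
    summary = file.path(cfg$out_dir, "summary.json"))
  utils::write.csv(similarity, paths$similarity, row.names = FALSE)
  utils::write.csv(segmentation, paths$segmentation, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, config_hash = hash,
         r_version = as.character(getRversion()),
         elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         summary = as.list(summary_nums)),
    paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("[done] %.1f min", as.numeric(difftime(Sys.time(), t0, units = "mins")))

  invisible(list(similarity = similarity, segmentation = segmentation,
                 tests = tests, summary = summary_nums, history = history,
                 checkpoint = ckpt, manifest = manifest, split = split,
                 paths = paths, config_hash = hash))
}
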