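#' Fit a contrast-removal translation model
#'
#' The modelling front end of the package: trains one of the three 3D
#' U-Net-like generators to map contrast-enhanced (T1ce) onto
#' non-contrast-enhanced (T1nce) volumes, optionally followed by
#' adversarial fine-tuning with the patch discriminator (warm-started
#' conditional GAN).  Returns a classed object with the usual modelling
#' methods: [predict.mri_translator()] translates new volumes,
#' [residuals.mri_translator()] reports per-pair brain-masked errors,
#' `plot()` draws the loss history, `coef()` returns the parameter arrays.
#'
#' @param pairs list of training pairs, each with `t1ce` and `t1nce`
#'   [volume3d()] members in `[0, 1]` (e.g. from [load_pairs()] or
#'   [make_phantom()] samples via [as_image_pair()]).
#' @param variant generator variant: `"att"`, `"res"` or `"trans"`.
#' @param adversarial if `TRUE`, pretrain the patch discriminator and
#'   fine-tune with [train_cgan()] after the L1 pretraining.
#' @param gen_cfg optional [generator_config()] (built from `variant` and
#'   the data shape when omitted).
#' @param train_cfg a [train_config()].
#' @param disc_cfg optional [discriminator_config()] for the adversarial
#'   stage.
#' @param pretrain_epochs,cgan_epochs epochs of the discriminator
#'   pretraining and of the joint adversarial stage.
#' @return An object of class `mri_translator`.
#' @export
fit_translator <- function(pairs, variant = c("att", "res", "trans"),
                           adversarial = FALSE,
                           gen_cfg = NULL, train_cfg = train_config(),
                           disc_cfg = NULL,
                           pretrain_epochs = 2L, cgan_epochs = 5L) {
  variant <- match.arg(variant)
  stopifnot(length(pairs) >= 1L)
  shape <- dim(vol_values(pairs[[1L]]$t1ce))
  if (is.null(gen_cfg))
    gen_cfg <- generator_config(variant = variant, input_shape = shape,
                                seed = derive_seed(train_cfg$seed, 41L))
  run <- train_generator_only(pairs, gen_cfg, train_cfg)
  history <- list(generator = run$history)
  ckpt <- run$checkpoint
  disc_ckpt <- NULL
  if (adversarial) {
    if (is.null(disc_cfg))
      disc_cfg <- discriminator_config(
        patch_size = as.integer(shape[1L] %/% 2L),
        seed = derive_seed(train_cfg$seed, 42L))
    pre_cfg <- train_cfg; pre_cfg$epochs <- as.integer(pretrain_epochs)
    pre <- pretrain_discriminator(pairs, ckpt, disc_cfg, pre_cfg)
    cg_cfg <- train_cfg; cg_cfg$epochs <- as.integer(cgan_epochs)
    cg <- train_cgan(pairs, ckpt, pre$checkpoint, cg_cfg)
    ckpt <- cg$checkpoint
    disc_ckpt <- cg$disc_checkpoint
    history$cgan <- cg$history
  }
  structure(list(checkpoint = ckpt, disc_checkpoint = disc_ckpt,
                 model = restore_model(ckpt), variant = gen_cfg$variant,
                 adversarial = adversarial, gen_cfg = gen_cfg,
                 train_cfg = train_cfg, history = history,
                 n_train = length(pairs), call = match.call()),
            class = "mri_translator")
}

#' Convert a phantom sample to a training pair
#'
#' @param sample a `phantom_sample` from [make_phantom()].
#' @return A pair list (`t1ce`, `t1nce`, `brain_mask`, quality labels,
#'   `subject_id`) as consumed by [fit_translator()] and [split_dataset()].
#' @export
as_image_pair <- function(sample) {
  stopifnot(inherits(sample, "phantom_sample"))
  list(t1ce = sample$t1ce, t1nce = sample$t1nce,
       brain_mask = sample$brain_mask,
       label_t1ce = quality_label(sample$grades_t1ce),
       label_t1nce = quality_label(sample$grades_t1nce),
       subject_id = sample$subject_id)
}

#' @export
print.mri_translator <- function(x, ...) {
  cat(sprintf("<mri_translator> %s%s generator, %d parameters\n",
              x$variant, if (x$adversarial) " + cGAN" else "",
              n_params(x$model)))
  h <- x$history$generator
  cat(sprintf("  trained on %d pairs, %d epochs; best L1 loss %.5f (epoch %d)\n",
              x$n_train, nrow(h), x$checkpoint$meta$loss %||% NA,
              x$checkpoint$meta$epoch %||% NA))
  invisible(x)
}

#' @export
summary.mri_translator <- function(object, ...) {
  h <- object$history$generator
  out <- list(variant = object$variant, adversarial = object$adversarial,
              n_parameters = n_params(object$model),
              n_train_pairs = object$n_train,
              epochs = nrow(h),
              first_epoch_loss = h$loss[1L],
              final_epoch_loss = h$loss[nrow(h)],
              best_epoch = object$checkpoint$meta$epoch,
              best_loss = object$checkpoint$meta$loss,
              input_shape = object$gen_cfg$input_shape)
  class(out) <- "summary.mri_translator"
  out
}

#' @export
print.summary.mri_translator <- function(x, ...) {
  cat(sprintf("Translation model: %s generator%s\n", x$variant,
              if (x$adversarial) " with adversarial fine-tuning" else ""))
  cat(sprintf("  input %s, %d parameters\n",
              paste(x$input_shape, collapse = "x"), x$n_parameters))
  cat(sprintf("  %d training pairs, %d epochs\n", x$n_train_pairs, x$epochs))
  cat(sprintf("  L1 loss: %.5f (first) -> %.5f (final); best %.5f at epoch %d\n",
              x$first_epoch_loss, x$final_epoch_loss, x$best_loss,
              x$best_epoch))
  invisible(x)
}

#' Translate volumes with a fitted model
#'
#' @param object an `mri_translator`.
#' @param newdata a [volume3d()] (T1ce), a list of volumes, or a list of
#'   pairs (the `t1ce` member is used).
#' @param ... unused.
#' @return A [volume3d()] (or list of them) with synthetic T1nce
#'   intensities in `[0, 1]`.
#' @export
predict.mri_translator <- function(object, newdata, ...) {
  one <- function(v) {
    if (is.list(v) && !is_volume3d(v) && !is.null(v$t1ce)) v <- v$t1ce
    translate_volume(object$model, v)
  }
  if (is_volume3d(newdata) || (is.array(newdata) && length(dim(newdata)) == 3L))
    return(one(newdata))
  lapply(newdata, one)
}

#' Per-pair residual errors of a fitted model
#'
#' Brain-masked mean absolute error (percent) between the translated T1ce
#' and the real T1nce of each pair.
#'
#' @param object an `mri_translator`.
#' @param pairs list of pairs with `t1ce`, `t1nce` and optionally
#'   `brain_mask`.
#' @param ... unused.
#' @return Named numeric vector of MAE (%) per pair.
#' @export
residuals.mri_translator <- function(object, pairs, ...) {
  vapply(pairs, function(p) {
    synth <- translate_volume(object$model, p$t1ce)
    msk <- p$brain_mask %||% array(TRUE, dim(p$t1nce$values))
    mae(p$t1nce, synth, msk)
  }, numeric(1))
}

#' @export
coef.mri_translator <- function(object, ...) {
  lapply(object$model$params, function(p) p$value)
}

#' Plot the training history
#'
#' @param x an `mri_translator`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mri_translator <- function(x, ...) {
  h <- x$history$generator
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training L1 loss",
                 main = sprintf("%s generator", x$variant), ...)
  if (!is.null(x$history$cgan)) {
    hc <- x$history$cgan
    graphics::lines(max(h$epoch) + hc$epoch, hc$L1_term, lty = 2)
    graphics::legend("topright", legend = c("L1 (pretraining)",
                                            "L1 term (cGAN)"),
                     lty = 1:2, bty = "n")
  }
  invisible(x)
}
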