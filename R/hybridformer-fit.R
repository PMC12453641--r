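# The modelling-style user interface: one fitting function returning a
# classed object with the usual methods.

#' Fit the hybrid CNN-transformer denoiser
#'
#' Trains the U-shaped residual-convolution / window-transformer network on
#' paired low-dose/normal-dose CT slices and returns a fitted-model object.
#' With `data = NULL` the built-in simulator generates the training pairs;
#' otherwise supply a list of `dose_pair`s (see [simulate_low_dose()]) or a
#' directory written by [write_pairs()].
#'
#' @param data `NULL`, a list of `dose_pair`s, or a dataset directory path.
#' @param config a [train_config()]; its `seed` drives every source of
#'   randomness.
#' @param out_dir optional run directory (resolved config, checkpoints,
#'   JSON-lines log).
#' @param verbose print per-epoch progress.
#' @return an object of class `hybridformer` with `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `simulate` and `plot` methods.
#' @examples
#' \donttest{
#' cfg <- train_config(model = hf_model_config(embed_dim = 16L,
#'                       depths_per_stage = c(1L, 1L), bottleneck_depth = 1L,
#'                       variant = "full"),
#'                     loss = loss_spec("charbonnier"),
#'                     batch_size = 4L, epochs = 2L, steps_per_epoch = 5L,
#'                     n_pairs = 6L, seed = 1L)
#' fit <- hybridformer(config = cfg)
#' denoised <- predict(fit, fit$fit$splits$val[[1]]$ldct)
#' }
#' @export
hybridformer <- function(data = NULL, config = train_config(),
                         out_dir = NULL, verbose = FALSE) {
  pairs <- if (is.character(data)) read_pairs(data) else data
  tr <- train(config, pairs = pairs, out_dir = out_dir, verbose = verbose)
  structure(list(fit = tr, config = config,
                 call = match.call()), class = "hybridformer")
}

#' @export
print.hybridformer <- function(x, ...) {
  cfg <- x$config
  cat("Hybrid CNN-transformer CT denoiser\n")
  cat(sprintf("  variant: %s  embed_dim: %d  stages: %s  window: %d\n",
              cfg$model$variant, cfg$model$embed_dim,
              paste(cfg$model$depths_per_stage, collapse = "/"),
              cfg$model$window_size))
  cat(sprintf("  parameters: %s  loss: %s  optimizer: %s\n",
              format(x$fit$model$parameter_count, big.mark = ","),
              cfg$loss$family, cfg$optimizer))
  lg <- x$fit$log
  cat(sprintf("  trained %d epochs (%d steps); best val PSNR %.2f dB (epoch %d)\n",
              nrow(lg), utils::tail(lg$step, 1),
              max(lg$val_psnr, na.rm = TRUE), x$fit$best_epoch))
  invisible(x)
}

#' @export
summary.hybridformer <- function(object, ...) {
  lg <- object$fit$log
  out <- list(
    config = object$config,
    parameter_count = object$fit$model$parameter_count,
    epochs = nrow(lg),
    final_train_loss = utils::tail(lg$train_loss, 1),
    best_epoch = object$fit$best_epoch,
    best_val_psnr = suppressWarnings(max(lg$val_psnr, na.rm = TRUE)),
    n_train = length(object$fit$splits$train),
    n_val = length(object$fit$splits$val),
    n_test = length(object$fit$splits$test))
  class(out) <- "summary.hybridformer"
  out
}

#' @export
print.summary.hybridformer <- function(x, ...) {
  cat(sprintf(
    "Fitted denoiser: %s parameters, %d/%d/%d train/val/test pairs\n",
    format(x$parameter_count, big.mark = ","), x$n_train, x$n_val, x$n_test))
  cat(sprintf("  %d epochs; final train loss %.5f\n", x$epochs,
              x$final_train_loss))
  cat(sprintf("  best validation PSNR %.2f dB at epoch %d\n",
              x$best_val_psnr, x$best_epoch))
  invisible(x)
}

#' Extract model parameters
#'
#' @param object a fitted `hybridformer`.
#' @param ... unused.
#' @return named list of numeric parameter arrays (flattened module paths
#'   as names).
#' @export
coef.hybridformer <- function(object, ...) {
  lapply(flatten_params(object$fit$model$params), function(p) p$v)
}

#' Denoise new slices with a fitted model
#'
#' @param object a fitted `hybridformer`.
#' @param newdata an H x W matrix, a list of matrices, or a list of
#'   `dose_pair`s (their `ldct` slices are used).
#' @param ... unused.
#' @return denoised image(s) matching the input structure.
#' @export
predict.hybridformer <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata[[1]]$ldct))
    newdata <- lapply(newdata, `[[`, "ldct")
  denoise(object$fit$model, newdata)
}

#' Predicted residual (noise) images
#'
#' The network predicts the restored slice as `input + residual`; this
#' returns the residual maps for the given slices (by default the held-out
#' validation inputs).
#'
#' @param object a fitted `hybridformer`.
#' @param newdata optional slices as in [predict.hybridformer()].
#' @param ... unused.
#' @return list of H x W residual matrices.
#' @export
residuals.hybridformer <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$fit$splits$val
  if (is.list(newdata) && !is.null(newdata[[1]]$ldct))
    newdata <- lapply(newdata, `[[`, "ldct")
  if (is.matrix(newdata)) newdata <- list(newdata)
  den <- denoise(object$fit$model, newdata)
  lapply(seq_along(newdata), function(i) den[[i]] - newdata[[i]])
}

#' Simulate paired slices from the fitted configuration
#'
#' Draws new synthetic low-dose/normal-dose pairs with the data settings
#' the model was configured with.
#'
#' @param object a fitted `hybridformer`.
#' @param nsim number of pairs.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `dose_pair`s.
#' @export
simulate.hybridformer <- function(object, nsim = 1, seed = 1L, ...) {
  cfg <- object$config
  make_paired_dataset(nsim, cfg$image_size, cfg$image_size, I0 = cfg$I0,
                      seed = seed, mode = cfg$sim_mode)
}

#' Plot training diagnostics
#'
#' Training loss and validation PSNR per epoch.
#'
#' @param x a fitted `hybridformer`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hybridformer <- function(x, ...) {
  lg <- x$fit$log
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$epoch, lg$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss", ...)
  if (any(is.finite(lg$val_psnr))) {
    graphics::plot(lg$epoch, lg$val_psnr, type = "b", pch = 16,
                   xlab = "epoch", ylab = "validation PSNR (dB)", ...)
  }
  invisible(x)
}
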