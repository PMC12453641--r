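# Training and evaluation orchestration: optimizers, the training loop with
# per-epoch validation and best-checkpoint tracking, batch inference,
# metric evaluation, and the ablation presets.

#' Training configuration
#'
#' Defaults mirror the reference training protocol: batch size 12, learning
#' rate 2e-4, AdamW (betas 0.9/0.999), 100 epochs, 64 x 64 patches.
#'
#' @param model an [hf_model_config()].
#' @param loss a [loss_spec()].
#' @param optimizer `"adamw"`, `"adam"`, `"nadam"` or `"sgd"`.
#' @param learning_rate positive step size.
#' @param betas length-2 moment-decay coefficients.
#' @param weight_decay decoupled weight decay (AdamW only).
#' @param batch_size patches per optimization step.
#' @param epochs training epochs.
#' @param steps_per_epoch optimization steps per epoch.
#' @param patch_size training patch side length.
#' @param seed master seed fixing data, initialisation and batching.
#' @param data_source `"synthetic"` (built-in simulator) or `"directory"`
#'   (paired image files; see [read_image()]).
#' @param n_pairs synthetic pairs to generate when `data_source =
#'   "synthetic"`.
#' @param image_size synthetic slice side length.
#' @param I0 synthetic incident photon count.
#' @param sim_mode simulator noise mode (see [simulate_low_dose()]).
#' @param split_ratios train/val/test weights for [split_pairs()].
#' @param lr_schedule `"constant"` or `"cosine"`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(model = hf_model_config(), loss = loss_spec(),
                         optimizer = c("adamw", "adam", "nadam", "sgd"),
                         learning_rate = 2e-4, betas = c(0.9, 0.999),
                         weight_decay = 0.01, batch_size = 12L,
                         epochs = 100L, steps_per_epoch = 25L,
                         patch_size = 64L, seed = 1L,
                         data_source = c("synthetic", "directory"),
                         n_pairs = 32L, image_size = 64L,
                         I0 = ldct_constants()$default_I0,
                         sim_mode = "sinogram_poisson",
                         split_ratios = c(8, 1, 1),
                         lr_schedule = c("constant", "cosine")) {
  optimizer <- match.arg(optimizer)
  data_source <- match.arg(data_source)
  lr_schedule <- match.arg(lr_schedule)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(list(model = model, loss = loss, optimizer = optimizer,
                 learning_rate = learning_rate, betas = betas,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed), data_source = data_source,
                 n_pairs = as.integer(n_pairs),
                 image_size = as.integer(image_size), I0 = I0,
                 sim_mode = sim_mode, split_ratios = split_ratios,
                 lr_schedule = lr_schedule),
            class = "train_config")
}

## ---- optimizers ----------------------------------------------------------

opt_init <- function(params_flat) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params_flat, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$v <- lapply(params_flat, function(p) array(0, dim(p$v) %||% length(p$v)))
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

opt_step <- function(params_flat, st, cfg, lr) {
  st$t <- st$t + 1L
  b1 <- cfg$betas[1]; b2 <- cfg$betas[2]
  eps <- 1e-8
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (i in seq_along(params_flat)) {
    p <- params_flat[[i]]
    g <- p$g
    if (is.null(g)) next
    switch(cfg$optimizer,
      sgd = {
        st$m[[i]] <- 0.9 * st$m[[i]] + g
        p$v <- p$v - lr * st$m[[i]]
      },
      adam = {
        st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
        st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
        p$v <- p$v - lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + eps)
      },
      nadam = {
        st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
        st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
        mh <- (b1 * st$m[[i]] + (1 - b1) * g) / c1
        p$v <- p$v - lr * mh / (sqrt(st$v[[i]] / c2) + eps)
      },
      adamw = {
        st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
        st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
        p$v <- p$v - lr * ((st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + eps) +
                             cfg$weight_decay * p$v)
      })
  }
  invisible(NULL)
}

## ---- training loop -------------------------------------------------------

batch_loss_ad <- function(model, ld, nd, P, B, cfg, extractor) {
  out <- hf_forward_mat(model, ld, P, P, training = TRUE, B = B)
  fam <- cfg$loss$family
  if (fam == "mse") return(ad_mse(out$y, nd))
  L <- ad_charbonnier(out$y, nd, cfg$loss$eps)
  if (fam == "compound" && cfg$loss$lambda > 0) {
    Lp <- loss_perceptual_ad(out$y, nd, P, P, extractor, cfg$loss$eps, B)
    L <- ad_add(L, ad_scale(Lp, cfg$loss$lambda))
  }
  L
}

# Batched eval-mode denoising of a list of same-sized matrices.
denoise_batch <- function(model, imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  B <- length(imgs)
  xm <- matrix(unlist(lapply(imgs, as.vector), use.names = FALSE), ncol = 1L)
  y <- nd_val(hf_forward_mat(model, xm, H, W, training = FALSE, B = B)$y)
  lapply(seq_len(B), function(i)
    matrix(y[(i - 1L) * H * W + seq_len(H * W)], H, W))
}

val_psnr_mean <- function(model, val_pairs) {
  if (length(val_pairs) == 0L) return(NA_real_)
  den <- denoise_batch(model, lapply(val_pairs, `[[`, "ldct"))
  mean(vapply(seq_along(val_pairs), function(i)
    psnr(val_pairs[[i]]$ndct, den[[i]], data_range = 1), 0))
}

#' Train the denoising network
#'
#' Optimizes the configured loss over paired low-dose/normal-dose patches.
#' Fully seeded: data generation, initialisation, batch order and noise all
#' derive from `config$seed`.  Validation PSNR is computed each epoch on the
#' held-out split and the best-validation parameters are retained.  A
#' non-finite loss aborts with a diagnostic record of the failing step.
#'
#' @param config a [train_config()].
#' @param pairs optional list of `dose_pair`s; if `NULL` and `data_source`
#'   is `"synthetic"`, pairs are generated from the config.
#' @param out_dir optional directory: receives the resolved config
#'   (`config.json`), per-epoch checkpoints (`last.ckpt`, `best.ckpt`) and
#'   an append-only JSON-lines log (`log.jsonl`).
#' @param verbose print per-epoch progress.
#' @return list of class `hf_training`: `model` (best-validation
#'   parameters), `last_model`, `log` (data.frame: epoch, step, train_loss,
#'   val_psnr, wall_time, seed), `best_epoch`, `splits` (the pairs used),
#'   `config`.
#' @export
train <- function(config = train_config(), pairs = NULL, out_dir = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(pairs)) {
    if (config$data_source != "synthetic")
      stop("pairs must be supplied unless data_source = 'synthetic'",
           call. = FALSE)
    pairs <- make_paired_dataset(config$n_pairs, config$image_size,
                                 config$image_size, I0 = config$I0,
                                 seed = config$seed, mode = config$sim_mode)
  }
  sp <- split_pairs(pairs, config$split_ratios)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_deep(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  model <- build_model(config$model, seed = config$seed)
  fp <- flatten_params(model$params)
  st <- opt_init(fp)
  extractor <- if (config$loss$family == "compound" && config$loss$lambda > 0)
    perceptual_extractor(config$loss$extractor, seed = config$seed,
                         num_scales = config$loss$num_scales) else NULL
  P <- config$patch_size
  B <- config$batch_size
  n_train <- length(sp$train)
  total_steps <- config$epochs * config$steps_per_epoch
  log <- vector("list", config$epochs)
  best <- list(psnr = -Inf, values = NULL, epoch = NA_integer_)
  t_start <- proc.time()[3]
  step <- 0L
  local_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (s in seq_len(config$steps_per_epoch)) {
        step <- step + 1L
        lr <- if (config$lr_schedule == "cosine")
          config$learning_rate * 0.5 * (1 + cos(pi * (step - 1) / total_steps))
        else config$learning_rate
        idx <- sample.int(n_train, B, replace = TRUE)
        ld <- matrix(0, B * P * P, 1L)
        nd <- matrix(0, B * P * P, 1L)
        for (b in seq_len(B)) {
          pr <- sp$train[[idx[b]]]
          pt <- sample_patches(pr, P, 1L,
                               seed = sample.int(2147483646L, 1L),
                               augment = TRUE)[[1L]]
          rows <- (b - 1L) * P * P + seq_len(P * P)
          ld[rows, 1L] <- pt$ldct
          nd[rows, 1L] <- pt$ndct
        }
        zero_grads(model$params)
        ad_tape_start()
        L <- batch_loss_ad(model, ld, nd, P, B, config, extractor)
        lv <- nd_val(L)
        if (!is.finite(lv)) {
          ad_tape_stop()
          diag_rec <- list(epoch = ep, step = step, train_loss = lv,
                           seed = config$seed, error = "non-finite loss")
          if (!is.null(out_dir))
            cat(jsonlite::toJSON(diag_rec, auto_unbox = TRUE, digits = NA), "\n",
                file = file.path(out_dir, "log.jsonl"), append = TRUE)
          stop("non-finite training loss at epoch ", ep, ", step ", step,
               call. = FALSE)
        }
        ad_backward(L)
        ad_tape_stop()
        opt_step(fp, st, config, lr)
        ep_loss <- ep_loss + lv
      }
      vp <- val_psnr_mean(model, sp$val)
      rec <- list(epoch = ep, step = step,
                  train_loss = ep_loss / config$steps_per_epoch,
                  val_psnr = vp, wall_time = proc.time()[3] - t_start,
                  seed = config$seed)
      log[[ep]] <- rec
      if (!is.null(out_dir)) {
        cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
            file = file.path(out_dir, "log.jsonl"), append = TRUE)
        save_checkpoint(model, file.path(out_dir, "last.ckpt"),
                        extra = list(epoch = ep))
      }
      if (is.na(vp) || vp >= best$psnr) {
        best$psnr <- if (is.na(vp)) best$psnr else vp
        best$values <- params_to_plain(model$params)
        best$epoch <- ep
        if (!is.null(out_dir))
          save_checkpoint(model, file.path(out_dir, "best.ckpt"),
                          extra = list(epoch = ep, val_psnr = vp))
      }
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.5f  val PSNR %.2f dB",
                        ep, config$epochs, ep_loss / config$steps_per_epoch,
                        vp))
    }
  })
  best_model <- structure(list(config = model$config,
                               params = plain_to_params(best$values),
                               seed = model$seed), class = "hf_model")
  best_model$parameter_count <- model_parameter_count(best_model)
  structure(list(model = best_model, last_model = model,
                 log = do.call(rbind, lapply(log, as.data.frame)),
                 best_epoch = best$epoch, splits = sp, config = config),
            class = "hf_training")
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Denoise images with a trained model
#'
#' Batch inference at native size (padding and cropping are handled
#' internally); two calls on the same input yield identical output.
#'
#' @param model an `hf_model`, an `hf_training` result, or the path to a
#'   checkpoint file.
#' @param images one H x W matrix or a list of them.
#' @return denoised image(s), matching the input structure.
#' @export
denoise <- function(model, images) {
  model <- resolve_model(model)
  single <- is.matrix(images)
  if (single) images <- list(images)
  sizes <- vapply(images, function(x) paste(dim(x), collapse = "x"), "")
  out <- vector("list", length(images))
  for (sz in unique(sizes)) {
    sel <- which(sizes == sz)
    out[sel] <- denoise_batch(model, images[sel])
  }
  if (single) out[[1L]] else out
}

resolve_model <- function(model) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "hf_training")) model <- model$model
  if (inherits(model, "hybridformer")) model <- model$fit$model
  if (!inherits(model, "hf_model"))
    stop("not a model, training result or checkpoint path", call. = FALSE)
  model
}

#' Evaluate a model on paired data
#'
#' Denoises each low-dose slice and scores it against the normal-dose
#' reference with PSNR/SSIM/FSIM; the unprocessed low-dose input is scored
#' as well (the noisy-input baseline row).
#'
#' @param model an `hf_model`, `hf_training`, or checkpoint path.
#' @param pairs list of `dose_pair`s.
#' @param data_range dynamic range of the slices (1 for the simulator's
#'   [0, 1] scale).
#' @return list of class `hf_evaluation` with `denoised` and `input`
#'   [evaluate_pairs()] reports.
#' @export
evaluate_model <- function(model, pairs, data_range = 1) {
  model <- resolve_model(model)
  if (length(pairs) == 0L) stop("no pairs to evaluate", call. = FALSE)
  bad <- vapply(pairs, function(p) is.null(p$ndct) || is.null(p$ldct), TRUE)
  if (any(bad)) stop("pairs must contain ndct and ldct", call. = FALSE)
  den <- denoise(model, lapply(pairs, `[[`, "ldct"))
  mk <- function(test_list)
    evaluate_pairs(lapply(seq_along(pairs), function(i)
      list(ref = pairs[[i]]$ndct, test = test_list[[i]],
           id = sprintf("pair_%03d", i))), data_range = data_range)
  structure(list(denoised = mk(den),
                 input = mk(lapply(pairs, `[[`, "ldct"))),
            class = "hf_evaluation")
}

#' @export
print.hf_evaluation <- function(x, ...) {
  cat("Noisy input:\n"); print(x$input)
  cat("\nDenoised:\n"); print(x$denoised)
  invisible(x)
}

## ---- ablation presets ----------------------------------------------------

hf_preset_names <- c("baseline", "use_catu", "use_rstb_no_ccafl",
                     "use_rstb", "full", "with_cal", "loss_mse",
                     "loss_charbonnier", "loss_compound")

#' Ablation preset configurations
#'
#' Returns a [train_config()] differing from the `"full"` configuration only
#' in the named component, so each ablation is a controlled comparison:
#' structural presets change the model variant, loss presets change only the
#' loss family.
#'
#' @param name one of `"baseline"`, `"use_catu"`, `"use_rstb_no_ccafl"`,
#'   `"use_rstb"`, `"full"`, `"with_cal"`, `"loss_mse"`,
#'   `"loss_charbonnier"`, `"loss_compound"`.
#' @param base optional `train_config` supplying every non-ablated setting
#'   (defaults to `train_config()`).
#' @return a `train_config`.
#' @export
ablation_preset <- function(name, base = train_config()) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% hf_preset_names))
    stop("unknown preset; valid names: ",
         paste(hf_preset_names, collapse = ", "), call. = FALSE)
  cfg <- base
  mc <- as.list(unclass(base$model))
  mc$num_stages <- NULL
  mk_model <- function(variant, dfrm) {
    mc$variant <- variant
    mc$dfrm_enabled <- dfrm
    do.call(hf_model_config, mc)
  }
  cfg$model <- switch(name,
    baseline = mk_model("baseline", FALSE),
    use_catu = mk_model("catu_only", FALSE),
    use_rstb_no_ccafl = mk_model("rstb_no_ccafl", FALSE),
    use_rstb = mk_model("rstb", FALSE),
    full = mk_model("full", TRUE),
    with_cal = mk_model("rstb_cal", TRUE),
    mk_model("full", TRUE))
  if (name %in% c("loss_mse", "loss_charbonnier", "loss_compound")) {
    fam <- sub("loss_", "", name)
    cfg$loss <- loss_spec(family = fam, eps = base$loss$eps,
                          lambda = base$loss$lambda,
                          extractor = base$loss$extractor,
                          num_scales = base$loss$num_scales)
  }
  cfg
}
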