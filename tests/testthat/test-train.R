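# Training orchestration: optimization progress, determinism, inference,
# evaluation and ablation presets.

fast_cfg <- function(seed = 1L, epochs = 2L, steps = 6L,
                     loss = loss_spec("charbonnier"),
                     learning_rate = 2e-3, optimizer = "adamw") {
  train_config(model = tiny_config(window_size = 8L),
               loss = loss, optimizer = optimizer,
               learning_rate = learning_rate, batch_size = 2L,
               epochs = epochs, steps_per_epoch = steps, patch_size = 32L,
               seed = seed, n_pairs = 8L, image_size = 48L,
               sim_mode = "image_mixed", split_ratios = c(6, 1, 1))
}

test_that("a short training run reduces the loss and logs every epoch", {
  out <- file.path(tempdir(), "run_smoke")
  tr <- train(fast_cfg(seed = 2L), out_dir = out)
  expect_s3_class(tr, "hf_training")
  expect_equal(nrow(tr$log), 2L)
  expect_lt(tail(tr$log$train_loss, 1), tr$log$train_loss[1])
  expect_true(all(is.finite(tr$log$train_loss)))
  expect_true(all(diff(tr$log$step) > 0))
  # run artefacts: resolved config, checkpoints, parseable JSONL log
  expect_true(file.exists(file.path(out, "config.json")))
  expect_true(file.exists(file.path(out, "best.ckpt")))
  expect_true(file.exists(file.path(out, "last.ckpt")))
  lines <- readLines(file.path(out, "log.jsonl"))
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$epoch, 2L)
  expect_equal(rec$train_loss, tail(tr$log$train_loss, 1),
               tolerance = 1e-12)
  cfg_back <- jsonlite::read_json(file.path(out, "config.json"),
                                  simplifyVector = TRUE)
  expect_equal(cfg_back$learning_rate, 2e-3)
  unlink(out, recursive = TRUE)
})

test_that("training is reproducible from one master seed", {
  tr1 <- train(fast_cfg(seed = 5L, epochs = 1L, steps = 4L))
  tr2 <- train(fast_cfg(seed = 5L, epochs = 1L, steps = 4L))
  expect_identical(tr1$log$train_loss, tr2$log$train_loss)
  expect_identical(tr1$log$val_psnr, tr2$log$val_psnr)
  v1 <- lapply(hf$flatten_params(tr1$model$params), function(p) p$v)
  v2 <- lapply(hf$flatten_params(tr2$model$params), function(p) p$v)
  expect_identical(v1, v2)
})

test_that("the perceptual extractor stays frozen through optimization", {
  ext_probe <- perceptual_extractor("tiny_random", seed = 3L)
  before <- lapply(ext_probe$stages, function(s) list(w = s$w$v, b = s$b$v))
  tr <- train(fast_cfg(seed = 3L, epochs = 1L, steps = 3L,
                       loss = loss_spec("compound", lambda = 0.1,
                                        extractor = "tiny_random")))
  after_ext <- perceptual_extractor("tiny_random", seed = 3L)
  after <- lapply(after_ext$stages, function(s) list(w = s$w$v, b = s$b$v))
  expect_identical(before, after)
  expect_true(all(is.finite(tr$log$train_loss)))
})

test_that("denoising is deterministic, shape-preserving, and identity for a zeroed head", {
  tr <- train(fast_cfg(seed = 7L, epochs = 1L, steps = 3L))
  x <- tr$splits$val[[1]]$ldct
  y1 <- denoise(tr, x)
  y2 <- denoise(tr$model, x)
  expect_identical(dim(y1), dim(x))
  expect_identical(y1, y2)
  ys <- denoise(tr$model, list(x, x + 0.01))
  expect_length(ys, 2L)
  expect_identical(ys[[1]], y1)

  m0 <- build_model(tiny_config(), seed = 1L)
  m0$params$final_w$v[] <- 0
  m0$params$final_b$v[] <- 0
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(m0, ck)
  expect_identical(denoise(ck, x), x)
})

test_that("evaluation reports one row per pair and matches across formats", {
  tr <- train(fast_cfg(seed = 9L, epochs = 1L, steps = 3L))
  test_pairs <- c(tr$splits$val, tr$splits$test)
  ev <- evaluate_model(tr, test_pairs, data_range = 1)
  expect_equal(nrow(ev$denoised$per_image), length(test_pairs))
  expect_equal(nrow(ev$input$per_image), length(test_pairs))
  # the identity model reproduces the noisy-input row exactly
  m0 <- build_model(tiny_config(), seed = 1L)
  m0$params$final_w$v[] <- 0
  m0$params$final_b$v[] <- 0
  ev0 <- evaluate_model(m0, test_pairs, data_range = 1)
  expect_equal(ev0$denoised$aggregate, ev0$input$aggregate,
               tolerance = 1e-12)
  expect_error(evaluate_model(tr, list(list(ndct = matrix(0, 4, 4)))),
               "ndct and ldct")
})

test_that("ablation presets are controlled single-component differences", {
  full <- ablation_preset("full")
  expect_identical(full$model$variant, "full")
  expect_true(full$model$dfrm_enabled)
  mse <- ablation_preset("loss_mse")
  comp <- ablation_preset("loss_compound")
  expect_identical(mse$model, comp$model)
  expect_identical(mse$optimizer, comp$optimizer)
  expect_identical(mse$loss$family, "mse")
  expect_identical(comp$loss$family, "compound")
  cal <- ablation_preset("with_cal")
  expect_identical(cal$model$variant, "rstb_cal")
  nc <- ablation_preset("use_rstb_no_ccafl")
  expect_identical(nc$model$variant, "rstb_no_ccafl")
  expect_false(nc$model$dfrm_enabled)
  expect_error(ablation_preset("nope"), "valid names")
})

test_that("the fitted-model interface exposes the standard methods", {
  cfg <- fast_cfg(seed = 11L, epochs = 2L, steps = 4L)
  fit <- hybridformer(config = cfg)
  expect_s3_class(fit, "hybridformer")
  expect_output(print(fit), "denoiser")
  s <- summary(fit)
  expect_output(print(s), "validation PSNR")
  cf <- coef(fit)
  expect_true(length(cf) > 50)
  expect_true(all(vapply(cf, is.numeric, TRUE)))
  x <- fit$fit$splits$val[[1]]$ldct
  y <- predict(fit, x)
  expect_identical(dim(y), dim(x))
  expect_identical(y, denoise(fit$fit$model, x))
  r <- residuals(fit, x)
  expect_equal(y, x + r[[1]], tolerance = 1e-12)
  sim <- simulate(fit, nsim = 2, seed = 4L)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]], "dose_pair")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("optimizer variants all reduce the loss on a short run", {
  for (opt in c("adamw", "adam", "nadam", "sgd")) {
    lr <- if (opt == "sgd") 5e-3 else 2e-3
    tr <- train(fast_cfg(seed = 13L, epochs = 2L, steps = 4L,
                         optimizer = opt, learning_rate = lr))
    expect_lt(tail(tr$log$train_loss, 1), tr$log$train_loss[1] * 1.05)
    expect_true(all(is.finite(tr$log$train_loss)))
  }
})
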