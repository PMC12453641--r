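# Blocks, sampling layers, variant construction and the full forward pass.

test_that("residual conv block: zero weights give identity, shapes preserved", {
  C <- 4L
  rp <- resconv_params(C)
  rp$w1$v[] <- 0; rp$b1$v[] <- 0; rp$w2$v[] <- 0; rp$b2$v[] <- 0
  x <- array(rnorm(C * 16 * 12), c(C, 16, 12))
  expect_identical(resconv(x, rp), x)

  set.seed(31)
  rp2 <- resconv_params(C)
  y <- resconv(x, rp2)
  expect_equal(dim(y), c(C, 16L, 12L))

  # linear regime against explicit convolution arithmetic on a tiny input
  rp3 <- resconv_params(1L)
  rp3$w1$v[] <- 0; rp3$b1$v <- 5            # ReLU inactive region avoided
  rp3$w2$v[] <- 0
  rp3$w2$v[5, 1] <- 0.1                      # centre tap only
  rp3$b2$v[] <- 0
  x3 <- matrix(rnorm(9), 3, 3)
  got <- resconv(x3, rp3)
  expect_equal(got, x3 + 0.1 * 5, tolerance = 1e-12)
})

test_that("RSTB: zero 1x1 convolutions give identity; channel routing is exact", {
  cfg <- tiny_config(window_size = 4L)
  C <- 8L
  bp <- rstb_params(C, cfg)
  bp$conv_in_w$v[] <- 0; bp$conv_in_b$v[] <- 0
  bp$conv_out_w$v[] <- 0; bp$conv_out_b$v[] <- 0
  x <- array(rnorm(C * 8 * 8), c(C, 8, 8))
  expect_equal(rstb_forward(x, bp, cfg), x, tolerance = 1e-14)
  expect_error(rstb_forward(array(rnorm(3 * 64), c(3, 8, 8)), bp, cfg),
               "even")

  # with identity 1x1 convs and pass-through branches the split/concat
  # round trip preserves channel ordering exactly
  bp2 <- rstb_params(C, hf_model_config(embed_dim = 16L,
                                        depths_per_stage = c(1L, 1L),
                                        bottleneck_depth = 1L,
                                        variant = "baseline",
                                        window_size = 4L))
  bp2$conv_in_w$v <- diag(C); bp2$conv_in_b$v[] <- 0
  bp2$conv_out_w$v <- diag(C); bp2$conv_out_b$v[] <- 0
  for (cu in bp2$branch2) {
    cu$attn$proj_w$v[] <- 0; cu$attn$proj_b$v[] <- 0
    cu$mlp_w2$v[] <- 0; cu$mlp_b2$v[] <- 0
  }
  expect_equal(rstb_forward(x, bp2, cfg), x + x, tolerance = 1e-12)

  # zeroed conv branch: output equals hand-composed CATU pathway plus skip
  cfg_r <- tiny_config(window_size = 4L)
  bp3 <- rstb_params(C, cfg_r)
  bp3$conv_in_w$v <- diag(C); bp3$conv_in_b$v[] <- 0
  for (nm in c("w1", "b1", "w2", "b2")) bp3$branch1[[nm]]$v[] <- 0
  f <- hf$fm_to_mat(x)
  y2 <- f$m[, 5:8]
  for (i in 1:2) {
    y2 <- hf$nd_val(hf$layer_catu(y2, 8L, 8L, bp3$branch2[[i]],
                                  alpha = cfg_r$alpha,
                                  shifted = (i %% 2L == 0L)))
  }
  ref <- cbind(f$m[, 1:4], y2) %*% bp3$conv_out_w$v +
    matrix(bp3$conv_out_b$v, 64, C, byrow = TRUE) + f$m
  expect_equal(rstb_forward(x, bp3, cfg_r),
               hf$mat_to_fm(ref, 8L, 8L, FALSE), tolerance = 1e-12)
})

test_that("down/upsampling satisfy the shape contracts and compose", {
  set.seed(32)
  d32 <- downsample(array(rnorm(32 * 32 * 32), c(32, 32, 32)),
                    downsample_params(32L))
  expect_equal(dim(d32), c(64L, 16L, 16L))
  d64 <- downsample(array(rnorm(16 * 64 * 64), c(16, 64, 64)),
                    downsample_params(16L))
  expect_equal(dim(d64), c(32L, 32L, 32L))

  u16 <- upsample(array(rnorm(64 * 16 * 16), c(64, 16, 16)),
                  upsample_params(64L))
  expect_equal(dim(u16), c(32L, 32L, 32L))
  u8 <- upsample(array(rnorm(4 * 8 * 8), c(4, 8, 8)), upsample_params(4L))
  expect_equal(dim(u8), c(2L, 16L, 16L))

  x <- array(rnorm(8 * 12 * 10), c(8, 12, 10))
  expect_equal(dim(upsample(downsample(x, downsample_params(8L)),
                            upsample_params(16L))), dim(x))
  expect_error(upsample(array(rnorm(3 * 64), c(3, 8, 8)),
                        upsample_params(4L)), "even")
})

test_that("DFRM halves internal resolution and contributes zero when merge is zeroed", {
  cfg <- tiny_config(window_size = 4L)
  C <- 8L
  dp <- dfrm_params(C, cfg, depth = 1L)          # zero-init merge
  x <- array(rnorm(C * 16 * 16), c(C, 16, 16))
  out <- dfrm_branch(x, dp, cfg)
  expect_equal(dim(out), dim(x))
  expect_true(all(out == 0))
  # patch embedding halves spatial dims
  pe <- hf$nd_val(hf$ad_conv2d(hf$fm_to_mat(x)$m, dp$pe_w, dp$pe_b,
                               16L, 16L, 2L, 2L, stride = 2L))
  expect_equal(nrow(pe), 8L * 8L)
  # odd input dims are padded then cropped, never an error
  x_odd <- array(rnorm(C * 15 * 13), c(C, 15, 13))
  expect_equal(dim(dfrm_branch(x_odd, dp, cfg)), dim(x_odd))
  # 32x32 and 64x64 keep their dims (non-zero merge)
  dp2 <- dfrm_params(C, cfg, depth = 1L, zero_merge = FALSE)
  for (n in c(32L, 64L)) {
    xn <- array(rnorm(C * n * n), c(C, n, n))
    expect_equal(dim(dfrm_branch(xn, dp2, cfg)), dim(xn))
  }
})

test_that("model construction is deterministic and variant-aware", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, seed = 5L)
  m2 <- build_model(cfg, seed = 5L)
  expect_identical(lapply(hf$flatten_params(m1$params), function(p) p$v),
                   lapply(hf$flatten_params(m2$params), function(p) p$v))

  counts <- vapply(c("baseline", "catu_only", "rstb_no_ccafl", "rstb",
                     "full"),
                   function(v) build_model(tiny_config(variant = v),
                                           1L)$parameter_count, 0)
  expect_true(all(diff(counts) > 0))

  base <- build_model(tiny_config(variant = "baseline"), 1L)
  nms <- names(hf$flatten_params(base$params))
  expect_false(any(grepl("\\.ca\\.", nms)))
  expect_false(any(grepl("dfrm", nms)))
})

test_that("decoder channel counts mirror the encoder reversed", {
  m <- build_model(tiny_config(), 1L)
  enc_c <- vapply(m$params$enc, function(s) s$blocks[[1]]$C, 0L)
  dec_c <- vapply(m$params$dec, function(s) s$blocks[[1]]$C, 0L)
  expect_identical(enc_c, dec_c)
})

test_that("full forward: residual identity, shape contract, determinism", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 6L)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- hybridformer_forward(x, m)
  expect_identical(out$restored, x + out$residual)
  expect_identical(hybridformer_forward(x, m)$restored, out$restored)

  m$params$final_w$v[] <- 0
  m$params$final_b$v[] <- 0
  expect_identical(hybridformer_forward(x, m)$restored, x)

  m2 <- build_model(cfg, seed = 6L)
  for (d in list(c(64L, 64L), c(100L, 72L), c(37L, 61L), c(16L, 16L))) {
    xi <- matrix(runif(prod(d)), d[1], d[2])
    oi <- hybridformer_forward(xi, m2)
    expect_equal(dim(oi$restored), d)
    expect_true(all(is.finite(oi$restored)))
  }
  expect_error(hybridformer_forward(matrix(1, 4, 4), m2), "window")
  expect_error(hybridformer_forward(array(1, c(2, 64, 64)), m2), "matrix")
})

test_that("every parameter group receives a finite non-zero gradient", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 7L)
  # lift deliberately zero-initialised projections off zero so no branch is
  # gradient-blocked by construction
  set.seed(71)
  for (p in hf$flatten_params(m$params))
    if (all(p$v == 0)) p$v[] <- rnorm(length(p$v), sd = 0.01)
  x <- matrix(runif(64 * 64 * 2), ncol = 1L)
  tgt <- matrix(runif(64 * 64 * 2), ncol = 1L)
  hf$zero_grads(m$params)
  hf$ad_tape_start()
  o <- hf$hf_forward_mat(m, x, 64L, 64L, training = TRUE, B = 2L)
  L <- hf$ad_charbonnier(o$y, tgt, 1e-3)
  hf$ad_backward(L)
  hf$ad_tape_stop()
  fp <- hf$flatten_params(m$params)
  for (nm in names(fp)) {
    g <- fp[[nm]]$g
    expect_false(is.null(g), info = nm)
    expect_true(all(is.finite(g)), info = nm)
    expect_gt(max(abs(g)), 0, label = paste("gradient of", nm))
  }
})

test_that("checkpoints round-trip parameters, config and version checks", {
  m <- build_model(tiny_config(variant = "rstb"), seed = 8L)
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f, extra = list(note = "unit"))
  m2 <- load_checkpoint(f)
  expect_identical(m2$config$variant, "rstb")
  expect_identical(lapply(hf$flatten_params(m$params), function(p) p$v),
                   lapply(hf$flatten_params(m2$params), function(p) p$v))
  expect_identical(attr(m2, "extra")$note, "unit")
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(hybridformer_forward(x, m2)$restored,
               hybridformer_forward(x, m)$restored)
  bad <- tempfile()
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
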