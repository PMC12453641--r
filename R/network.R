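# The U-shaped denoising network: residual-convolution / window-transformer
# fusion blocks (RSTB), the deep feature refinement module (DFRM),
# down/upsampling, variant construction and checkpoint (de)serialisation.

hf_variants <- c("baseline", "catu_only", "rstb_no_ccafl", "rstb",
                 "full", "rstb_cal")

#' Model architecture configuration
#'
#' All architectural hyperparameters of the network.  Spatial dimensions are
#' handled by reflect padding to a multiple of `window_size * 2^num_stages`
#' and exact cropping, so any input at least one window large is accepted.
#'
#' Ablation variants share one skeleton (1x1 conv, channel split, two
#' branches, concat, 1x1 conv, outer residual) and differ only in the named
#' component: `baseline` uses plain window-transformer layers (identity conv
#' branch, no channel attention), `catu_only` adds the CCAFL gate,
#' `rstb_no_ccafl` adds the residual-convolution branch instead, `rstb` has
#' both, `full` additionally enables the DFRM encoder branches, and
#' `rstb_cal` replaces CCAFL by the plain channel attention layer.
#'
#' @param in_channels input image channels (1 for CT).
#' @param embed_dim channels after the shallow 3x3 convolution.
#' @param depths_per_stage integer vector: RSTBs per encoder/decoder stage;
#'   its length is the number of stages.
#' @param bottleneck_depth RSTBs in the bottleneck.
#' @param window_size attention window side M.
#' @param alpha scale of the channel-attention branch inside each CATU.
#' @param variant one of `"baseline"`, `"catu_only"`, `"rstb_no_ccafl"`,
#'   `"rstb"`, `"full"`, `"rstb_cal"`.
#' @param dfrm_enabled build DFRM branches (forced `TRUE` for `variant =
#'   "full"`).
#' @param catu_per_rstb transformer units per RSTB (alternating
#'   unshifted/shifted windows).
#' @param msa_on_raw_input feed the raw residual stream (not the normalised
#'   one) to window attention, honouring the pre-norm-free formulation.
#' @param mlp_ratio MLP expansion ratio inside each CATU.
#' @return an object of class `hf_config`.
#' @export
hf_model_config <- function(in_channels = 1L, embed_dim = 32L,
                            depths_per_stage = c(2L, 2L, 2L),
                            bottleneck_depth = 2L, window_size = 8L,
                            alpha = 0.01, variant = "full",
                            dfrm_enabled = identical(variant, "full"),
                            catu_per_rstb = 2L, msa_on_raw_input = FALSE,
                            mlp_ratio = 4L) {
  variant <- match.arg(variant, hf_variants)
  if (identical(variant, "full")) dfrm_enabled <- TRUE
  if (embed_dim < 2L || embed_dim %% 2L != 0L)
    stop("embed_dim must be even and >= 2", call. = FALSE)
  if (length(depths_per_stage) < 1L || any(depths_per_stage < 1L))
    stop("depths_per_stage must be positive integers", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  structure(list(
    in_channels = as.integer(in_channels),
    embed_dim = as.integer(embed_dim),
    num_stages = length(depths_per_stage),
    depths_per_stage = as.integer(depths_per_stage),
    bottleneck_depth = as.integer(bottleneck_depth),
    window_size = as.integer(window_size),
    alpha = alpha,
    variant = variant,
    dfrm_enabled = isTRUE(dfrm_enabled),
    catu_per_rstb = as.integer(catu_per_rstb),
    msa_on_raw_input = isTRUE(msa_on_raw_input),
    mlp_ratio = as.integer(mlp_ratio)
  ), class = "hf_config")
}

variant_uses_resconv <- function(variant) {
  variant %in% c("rstb_no_ccafl", "rstb", "full", "rstb_cal")
}

variant_ca <- function(variant) {
  switch(variant,
         baseline = "none", rstb_no_ccafl = "none",
         catu_only = "ccafl", rstb = "ccafl", full = "ccafl",
         rstb_cal = "cal")
}

## ---- parameter constructors ---------------------------------------------

#' @rdname resconv
#' @param C channel count.
#' @param std truncated-normal init standard deviation.
#' @export
resconv_params <- function(C, std = 0.02) {
  list(w1 = mk_w(9L * C, C, std), b1 = mk_b(C),
       w2 = mk_w(9L * C, C, std), b2 = mk_b(C), C = as.integer(C))
}

#' @rdname rstb_forward
#' @param C channel count of the block input (must be even).
#' @param config an `hf_config` supplying window size, variant, alpha and
#'   related switches.
#' @param std truncated-normal init standard deviation.
#' @export
rstb_params <- function(C, config = hf_model_config(), std = 0.02) {
  if (C %% 2L != 0L)
    stop("RSTB requires an even channel count", call. = FALSE)
  Ch <- C %/% 2L
  v <- config$variant
  list(
    conv_in_w = mk_w(C, C, std), conv_in_b = mk_b(C),
    branch1 = if (variant_uses_resconv(v)) resconv_params(Ch, std) else NULL,
    branch2 = lapply(seq_len(config$catu_per_rstb), function(i)
      catu_params(Ch, config$window_size,
                  num_heads = max(1L, Ch %/% 32L),
                  use_ca = variant_ca(v),
                  mlp_ratio = config$mlp_ratio, std = std)),
    conv_out_w = mk_w(C, C, std), conv_out_b = mk_b(C),
    C = as.integer(C)
  )
}

#' @rdname downsample
#' @param C input channel count.
#' @param std truncated-normal init standard deviation.
#' @export
downsample_params <- function(C, std = 0.02) {
  list(w = mk_w(16L * C, 2L * C, std), b = mk_b(2L * C), C = as.integer(C))
}

#' @rdname upsample
#' @param C input channel count (must be even).
#' @param std truncated-normal init standard deviation.
#' @export
upsample_params <- function(C, std = 0.02) {
  if (C %% 2L != 0L) stop("upsample requires even C", call. = FALSE)
  list(w = mk_w(C, 4L * (C %/% 2L), std), b = mk_b(C %/% 2L),
       C = as.integer(C))
}

#' @rdname dfrm_branch
#' @param C channel count of the stage input.
#' @param config an `hf_config`.
#' @param depth number of internal RSTBs.
#' @param std truncated-normal init standard deviation.
#' @param zero_merge zero-initialise the merge projection so the branch
#'   starts as an exact no-op (the default).
#' @export
dfrm_params <- function(C, config = hf_model_config(), depth = 1L,
                        std = 0.02, zero_merge = TRUE) {
  merge_w <- if (zero_merge) ad_param(matrix(0, C, C)) else mk_w(C, C, std)
  list(
    pe_w = mk_w(4L * C, C, std), pe_b = mk_b(C),
    blocks = lapply(seq_len(depth), function(i) rstb_params(C, config, std)),
    merge_w = merge_w, merge_b = mk_b(C), C = as.integer(C)
  )
}

## ---- internal forwards ---------------------------------------------------

layer_resconv <- function(x, H, W, p, B = 1L) {
  h <- ad_relu(ad_conv2d(x, p$w1, p$b1, H, W, 3L, B = B))
  h <- ad_conv2d(h, p$w2, p$b2, H, W, 3L, B = B)
  ad_add(h, x)
}

layer_rstb <- function(x, H, W, p, config, training = FALSE, B = 1L) {
  h <- ad_linear(x, p$conv_in_w, p$conv_in_b)
  Ch <- p$C %/% 2L
  x1 <- ad_cols(h, seq_len(Ch))
  x2 <- ad_cols(h, Ch + seq_len(Ch))
  y1 <- if (is.null(p$branch1)) x1 else layer_resconv(x1, H, W, p$branch1, B)
  y2 <- x2
  for (i in seq_along(p$branch2)) {
    y2 <- layer_catu(y2, H, W, p$branch2[[i]], alpha = config$alpha,
                     shifted = (i %% 2L == 0L), training = training,
                     msa_on_raw_input = config$msa_on_raw_input, B = B)
  }
  z <- ad_linear(ad_cbind(y1, y2), p$conv_out_w, p$conv_out_b)
  ad_add(z, x)
}

layer_downsample <- function(x, H, W, p, B = 1L) {
  ad_conv2d(x, p$w, p$b, H, W, 4L, 4L, stride = 2L, B = B)
}

layer_upsample <- function(x, H, W, p, B = 1L) {
  ad_deconv2(x, p$w, p$b, H, W, B = B)
}

layer_dfrm <- function(x, H, W, p, config, training = FALSE, B = 1L) {
  h <- ad_conv2d(x, p$pe_w, p$pe_b, H, W, 2L, 2L, stride = 2L, B = B)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  for (b in p$blocks) h <- layer_rstb(h, H2, W2, b, config, training, B)
  h <- ad_bilinear_up2(h, H2, W2, B)
  ad_linear(h, p$merge_w, p$merge_b)
}

## ---- model construction --------------------------------------------------

#' Build a model with deterministic initialisation
#'
#' Constructs all parameters of the configured network.  Projection weights
#' use truncated-normal initialisation (sd 0.02), norms start at identity,
#' relative-position bias tables and DFRM merge projections start at zero.
#' The same `config` and `seed` always produce bit-identical parameters.
#'
#' @param config an [hf_model_config()].
#' @param seed integer seed controlling the initialisation.
#' @return an object of class `hf_model`: list with `config`, `params`
#'   (nested parameter nodes), `parameter_count` and `seed`.
#' @export
build_model <- function(config = hf_model_config(), seed = 1L) {
  if (!inherits(config, "hf_config"))
    stop("config must be an hf_config", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  D <- config$embed_dim
  S <- config$num_stages
  enc <- vector("list", S)
  for (i in seq_len(S)) {
    C <- D * 2L^(i - 1L)
    enc[[i]] <- list(
      blocks = lapply(seq_len(config$depths_per_stage[i]), function(b)
        rstb_params(C, config)),
      dfrm = if (config$dfrm_enabled && i >= 2L)
        dfrm_params(C, config, depth = 1L) else NULL,
      down = downsample_params(C)
    )
  }
  Cb <- D * 2L^S
  bott <- lapply(seq_len(config$bottleneck_depth), function(b)
    rstb_params(Cb, config))
  dec <- vector("list", S)
  for (i in seq_len(S)) {           # decoder stage i mirrors encoder stage i
    C <- D * 2L^(i - 1L)
    dec[[i]] <- list(
      up = upsample_params(2L * C),
      merge_w = mk_w(2L * C, C), merge_b = mk_b(C),
      blocks = lapply(seq_len(config$depths_per_stage[i]), function(b)
        rstb_params(C, config))
    )
  }
  params <- list(
    shallow_w = mk_w(9L * config$in_channels, D), shallow_b = mk_b(D),
    enc = enc, bottleneck = bott, dec = dec,
    final_w = mk_w(9L * D, config$in_channels),
    final_b = mk_b(config$in_channels)
  )
  m <- structure(list(config = config, params = params,
                      seed = as.integer(seed)), class = "hf_model")
  m$parameter_count <- model_parameter_count(m)
  m
}

#' Count trainable parameters of a model
#'
#' @param model an `hf_model`.
#' @return integer total number of scalar parameters.
#' @export
model_parameter_count <- function(model) {
  sum(vapply(flatten_params(model$params), function(p) length(p$v), 0))
}

# Full forward pass on a (B*H*W) x 1 matrix of B stacked image blocks with
# per-image spatial dims (H, W).  Returns list(y, r) on the original dims.
hf_forward_mat <- function(model, xm, H, W, training = FALSE, B = 1L) {
  cfg <- model$config
  p <- model$params
  S <- cfg$num_stages
  mult <- cfg$window_size * 2L^S
  pd <- pad_to_multiple_idx(H, W, mult)
  h <- if (is.matrix(xm)) xm else matrix(xm, ncol = 1L)
  hp <- h[bat_idx(pd$idx, B, H * W), , drop = FALSE]
  Hc <- pd$Hp; Wc <- pd$Wp
  f <- ad_conv2d(hp, p$shallow_w, p$shallow_b, Hc, Wc, 3L, B = B)
  skips <- vector("list", S)
  dims <- vector("list", S)
  for (i in seq_len(S)) {
    st <- p$enc[[i]]
    z <- f
    for (b in st$blocks) z <- layer_rstb(z, Hc, Wc, b, cfg, training, B)
    if (!is.null(st$dfrm))
      z <- ad_add(z, layer_dfrm(f, Hc, Wc, st$dfrm, cfg, training, B))
    skips[[i]] <- z
    dims[[i]] <- c(Hc, Wc)
    f <- layer_downsample(z, Hc, Wc, st$down, B)
    Hc <- Hc %/% 2L; Wc <- Wc %/% 2L
  }
  for (b in p$bottleneck) f <- layer_rstb(f, Hc, Wc, b, cfg, training, B)
  for (i in seq.int(S, 1L)) {
    st <- p$dec[[i]]
    f <- layer_upsample(f, Hc, Wc, st$up, B)
    Hc <- dims[[i]][1L]; Wc <- dims[[i]][2L]
    f <- ad_linear(ad_cbind(skips[[i]], f), st$merge_w, st$merge_b)
    for (b in st$blocks) f <- layer_rstb(f, Hc, Wc, b, cfg, training, B)
  }
  r <- ad_conv2d(f, p$final_w, p$final_b, Hc, Wc, 3L, B = B)
  # crop padding away; Y = X + R exactly on the original support
  rcrop <- ad_gather(r, bat_idx(pd$crop, B, pd$Hp * pd$Wp))
  y <- ad_add(rcrop, h)
  list(y = y, r = rcrop)
}

## ---- exported operations -------------------------------------------------

#' Residual convolution block
#'
#' Two 3x3 convolutions with a ReLU between them and an identity skip
#' connection; output shape equals input shape.
#'
#' @param feature an H x W matrix or C x H x W array.
#' @param params parameters from `resconv_params()`.
#' @return feature of identical shape and layout.
#' @export
resconv <- function(feature, params) {
  f <- fm_to_mat(feature)
  if (f$C != params$C)
    stop("channel count of feature and params disagree", call. = FALSE)
  o <- nd_val(layer_resconv(f$m, f$H, f$W, params))
  mat_to_fm(o, f$H, f$W, f$was_matrix)
}

#' Residual convolution + window transformer fusion block (RSTB)
#'
#' A 1x1 convolution splits the feature into two half-width streams; one
#' passes through a residual convolution block, the other through a chain of
#' combined attention transformer units (alternating unshifted/shifted
#' windows); the streams are concatenated, merged by a second 1x1
#' convolution, and added to the block input.
#'
#' @param feature an H x W matrix or C x H x W array with even C.  Spatial
#'   dims are reflect-padded to a window multiple and cropped back.
#' @param params parameters from [rstb_params()].
#' @param config the `hf_config` the parameters were built for.
#' @return feature of identical shape and layout.
#' @export
rstb_forward <- function(feature, params, config = hf_model_config()) {
  f <- fm_to_mat(feature)
  if (f$C %% 2L != 0L)
    stop("RSTB requires an even channel count", call. = FALSE)
  if (f$C != params$C)
    stop("channel count of feature and params disagree", call. = FALSE)
  pd <- pad_to_multiple_idx(f$H, f$W, config$window_size)
  m <- f$m[pd$idx, , drop = FALSE]
  o <- nd_val(layer_rstb(m, pd$Hp, pd$Wp, params, config))
  mat_to_fm(o[pd$crop, , drop = FALSE], f$H, f$W, f$was_matrix)
}

#' Deep feature refinement branch (DFRM)
#'
#' Patch-embeds the stage input to half resolution (2x2 stride-2
#' convolution), refines it with internal RSTBs, bilinearly upsamples back
#' and applies a merge projection, so the result can be summed with the
#' stage's main RSTB output.  The merge projection is zero-initialised by
#' default, making a fresh branch an exact no-op.
#'
#' @param stage_input an H x W matrix or C x H x W array; odd spatial dims
#'   are padded and cropped, never an error.
#' @param params parameters from [dfrm_params()].
#' @param config the `hf_config` the parameters were built for.
#' @return feature with the spatial dims of `stage_input`.
#' @export
dfrm_branch <- function(stage_input, params, config = hf_model_config()) {
  f <- fm_to_mat(stage_input)
  if (f$C != params$C)
    stop("channel count of feature and params disagree", call. = FALSE)
  mult <- 2L * config$window_size   # half-res features still window-sized
  pd <- pad_to_multiple_idx(f$H, f$W, mult)
  m <- f$m[pd$idx, , drop = FALSE]
  o <- nd_val(layer_dfrm(m, pd$Hp, pd$Wp, params, config))
  mat_to_fm(o[pd$crop, , drop = FALSE], f$H, f$W, f$was_matrix)
}

#' Downsampling layer
#'
#' 4x4 convolution with stride 2 (reflect padding): halves both spatial
#' dimensions and doubles the channel count.
#'
#' @param feature an H x W matrix or C x H x W array.
#' @param params parameters from `downsample_params()`.
#' @return a 2C x H/2 x W/2 array.
#' @export
downsample <- function(feature, params) {
  f <- fm_to_mat(feature)
  if (f$C != params$C)
    stop("channel count of feature and params disagree", call. = FALSE)
  o <- layer_downsample(f$m, f$H, f$W, params)
  mat_to_fm(nd_val(o), attr(o, "Ho"), attr(o, "Wo"), FALSE)
}

#' Upsampling layer
#'
#' 2x2 transposed convolution with stride 2: doubles both spatial dimensions
#' and halves the channel count.
#'
#' @param feature an H x W matrix or C x H x W array with even C.
#' @param params parameters from `upsample_params()`.
#' @return a C/2 x 2H x 2W array.
#' @export
upsample <- function(feature, params) {
  f <- fm_to_mat(feature)
  if (f$C %% 2L != 0L)
    stop("upsample requires an even channel count", call. = FALSE)
  if (f$C != params$C)
    stop("channel count of feature and params disagree", call. = FALSE)
  o <- nd_val(layer_upsample(f$m, f$H, f$W, params))
  mat_to_fm(o, 2L * f$H, 2L * f$W, FALSE)
}

#' Full network forward pass
#'
#' Runs the U-shaped encoder-decoder on a single-channel slice and returns
#' the restored image together with the predicted residual, satisfying
#' `restored = input + residual` exactly.  Any input size of at least one
#' window is handled by reflect padding and exact cropping.
#'
#' @param x an H x W numeric matrix (one grayscale slice).
#' @param model an `hf_model` from [build_model()].
#' @return a list of class `denoised_result` with elements `restored` and
#'   `residual` (H x W matrices).
#' @export
hybridformer_forward <- function(x, model) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric H x W matrix", call. = FALSE)
  if (min(dim(x)) < model$config$window_size)
    stop("input smaller than one attention window", call. = FALSE)
  xm <- matrix(as.vector(x), ncol = 1L)
  out <- hf_forward_mat(model, xm, nrow(x), ncol(x), training = FALSE)
  structure(list(restored = matrix(nd_val(out$y), nrow(x), ncol(x)),
                 residual = matrix(nd_val(out$r), nrow(x), ncol(x))),
            class = "denoised_result")
}

## ---- checkpoint serialisation -------------------------------------------

params_to_plain <- function(p) {
  if (is_node(p)) return(list(.param = p$v))
  if (is.environment(p)) return(list(.bnstats = list(mean = p$mean,
                                                     var = p$var)))
  if (is.list(p)) return(lapply(p, params_to_plain))
  p
}

plain_to_params <- function(p) {
  if (is.list(p)) {
    if (!is.null(p$.param)) return(ad_param(p$.param))
    if (!is.null(p$.bnstats)) {
      e <- new.env(parent = emptyenv())
      e$mean <- p$.bnstats$mean; e$var <- p$.bnstats$var
      return(e)
    }
    return(lapply(p, plain_to_params))
  }
  p
}

#' Save a model checkpoint
#'
#' Writes a versioned archive holding the configuration and every named
#' parameter array (including running normalisation statistics).
#'
#' @param model an `hf_model`.
#' @param path destination file.
#' @param extra optional named list stored alongside (e.g. training state).
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  obj <- list(format = "hybridformer-checkpoint", version = 1L,
              config = unclass(model$config), seed = model$seed,
              values = params_to_plain(model$params), extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return an `hf_model` with restored parameters; training extras, if any,
#'   are attached as attribute `"extra"`.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint: ", conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "hybridformer-checkpoint") ||
      is.null(obj$version))
    stop("not a versioned hybridformer checkpoint", call. = FALSE)
  if (obj$version != 1L)
    stop("unsupported checkpoint version: ", obj$version, call. = FALSE)
  cfg <- do.call(hf_model_config, obj$config[setdiff(names(obj$config),
                                                     "num_stages")])
  m <- structure(list(config = cfg, params = plain_to_params(obj$values),
                      seed = obj$seed), class = "hf_model")
  m$parameter_count <- model_parameter_count(m)
  attr(m, "extra") <- obj$extra
  m
}
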