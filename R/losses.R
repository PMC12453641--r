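# Charbonnier, multi-scale perceptual and compound losses, plus MSE for the
# loss ablation.

#' Loss specification
#'
#' @param family `"mse"`, `"charbonnier"` or `"compound"` (Charbonnier plus
#'   lambda times the multi-scale perceptual term).
#' @param eps Charbonnier smoothing constant (> 0, default 1e-3).
#' @param lambda non-negative weight of the perceptual term.
#' @param extractor feature extractor for the perceptual term; see
#'   [perceptual_extractor()].
#' @param num_scales number of extractor stages averaged by the perceptual
#'   term.
#' @return an object of class `loss_spec`.
#' @export
loss_spec <- function(family = c("compound", "charbonnier", "mse"),
                      eps = 1e-3, lambda = 0.1,
                      extractor = "tiny_random", num_scales = 4L) {
  family <- match.arg(family)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (num_scales < 1L) stop("num_scales must be >= 1", call. = FALSE)
  structure(list(family = family, eps = eps, lambda = lambda,
                 extractor = extractor, num_scales = as.integer(num_scales)),
            class = "loss_spec")
}

check_same_shape <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target must have identical shapes", call. = FALSE)
  invisible(NULL)
}

#' Charbonnier loss
#'
#' Smooth robust penalty `mean(sqrt(d^2 + eps^2))` over per-pixel
#' differences d, an everywhere-differentiable surrogate for absolute
#' error.  Its minimum, attained at `pred == target`, is `eps`.
#'
#' @param pred,target numeric arrays of identical shape.
#' @param eps smoothing constant (> 0).
#' @return scalar loss.
#' @examples
#' charbonnier_loss(matrix(1, 4, 4), matrix(1, 4, 4))  # == 1e-3
#' @export
charbonnier_loss <- function(pred, target, eps = 1e-3) {
  check_same_shape(pred, target)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  nd_val(ad_charbonnier(pred, target, eps))
}

#' Mean squared error loss
#'
#' @param pred,target numeric arrays of identical shape.
#' @return scalar mean of squared per-pixel differences.
#' @export
mse_loss <- function(pred, target) {
  check_same_shape(pred, target)
  nd_val(ad_mse(pred, target))
}

## ---- perceptual feature extractor ---------------------------------------

#' Construct a frozen perceptual feature extractor
#'
#' The perceptual term compares deep features of the restored and reference
#' image under a fixed (never trained) convolutional extractor with
#' `num_scales` stages, each a stride-2 3x3 convolution followed by a leaky
#' ReLU.  `"tiny_random"` builds a small seeded random-weight extractor that
#' needs no downloaded weights.  The `"resnet50_pretrained"` and
#' `"resnet50_random"` choices require external weight files; when these are
#' unavailable the constructor falls back, with a warning, to the seeded
#' random-weight extractor.  `"identity"` exposes the raw image as a single
#' stage (so the perceptual loss collapses to the Charbonnier loss).
#'
#' @param type extractor family.
#' @param seed seed fixing the random weights.
#' @param num_scales number of stages.
#' @param base_width channels of the first stage (doubled per stage, capped
#'   at 64).
#' @return an object of class `perceptual_extractor`.
#' @export
perceptual_extractor <- function(type = c("tiny_random",
                                          "resnet50_pretrained",
                                          "resnet50_random", "identity"),
                                 seed = 1L, num_scales = 4L,
                                 base_width = 8L) {
  type <- match.arg(type)
  if (type %in% c("resnet50_pretrained", "resnet50_random")) {
    warning("no ", type, " weights available offline; ",
            "falling back to the seeded random-weight extractor",
            call. = FALSE)
    type <- "tiny_random"
  }
  if (type == "identity") {
    return(structure(list(type = "identity", num_scales = 1L,
                          in_channels = 1L), class = "perceptual_extractor"))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  widths <- pmin(base_width * 2L^(seq_len(num_scales) - 1L), 64L)
  cin <- 3L
  stages <- vector("list", num_scales)
  for (j in seq_len(num_scales)) {
    stages[[j]] <- list(w = mk_w(9L * cin, widths[j], std = 0.1),
                        b = mk_b(widths[j]))
    cin <- widths[j]
  }
  structure(list(type = "tiny_random", stages = stages, widths = widths,
                 num_scales = as.integer(num_scales), in_channels = 3L,
                 seed = as.integer(seed)),
            class = "perceptual_extractor")
}

# Stage features of a (B*H*W) x 1 node/matrix; list of nodes.
extractor_features <- function(x, H, W, ext, B = 1L) {
  if (ext$type == "identity") return(list(x))
  h <- ad_cbind(ad_cbind(x, x), x)  # replicate grayscale to 3 channels
  Hc <- H; Wc <- W
  feats <- vector("list", ext$num_scales)
  for (j in seq_len(ext$num_scales)) {
    h <- ad_lrelu(ad_conv2d(h, ext$stages[[j]]$w, ext$stages[[j]]$b,
                            Hc, Wc, 3L, stride = 2L, B = B), 0.2)
    Hc <- (Hc + 1L) %/% 2L  # stride-2 'same' conv: ceil(n/2)
    Wc <- (Wc + 1L) %/% 2L
    feats[[j]] <- h
  }
  feats
}

# Autodiff perceptual loss used by the trainer.
loss_perceptual_ad <- function(pred, target, H, W, ext, eps = 1e-3,
                               B = 1L) {
  fp <- extractor_features(pred, H, W, ext, B)
  ft <- extractor_features(target, H, W, ext, B)
  M <- length(fp)
  tot <- ad_charbonnier(fp[[1L]], nd_val(ft[[1L]]), eps)
  if (M > 1L) {
    for (j in 2L:M) tot <- ad_add(tot, ad_charbonnier(fp[[j]],
                                                      nd_val(ft[[j]]), eps))
  }
  ad_scale(tot, 1 / M)
}

#' Multi-scale perceptual loss
#'
#' Mean over extractor stages of the Charbonnier distance between the deep
#' features of `pred` and `target` under a frozen extractor.  Equals `eps`
#' iff `pred == target`.
#'
#' @param pred,target H x W numeric matrices of identical shape.
#' @param extractor a [perceptual_extractor()] (or a type string passed to
#'   that constructor).
#' @param eps Charbonnier smoothing constant.
#' @return scalar loss.
#' @export
perceptual_loss <- function(pred, target, extractor = "tiny_random",
                            eps = 1e-3) {
  check_same_shape(pred, target)
  if (!inherits(extractor, "perceptual_extractor"))
    extractor <- perceptual_extractor(extractor)
  pm <- matrix(as.vector(pred), ncol = 1L)
  tm <- matrix(as.vector(target), ncol = 1L)
  nd_val(loss_perceptual_ad(pm, tm, nrow(pred), ncol(pred), extractor, eps))
}

#' Compound loss
#'
#' `L = L_charbonnier + lambda * L_perceptual`.  With `lambda = 0` this is
#' exactly the Charbonnier loss; at `pred == target` it equals
#' `eps * (1 + lambda)`.
#'
#' @param pred,target H x W numeric matrices of identical shape.
#' @param spec a [loss_spec()]; its `family` selects mse/charbonnier/compound.
#' @param extractor optional pre-built [perceptual_extractor()] (otherwise
#'   constructed from `spec$extractor`).
#' @return scalar loss.
#' @export
compound_loss <- function(pred, target, spec = loss_spec(),
                          extractor = NULL) {
  check_same_shape(pred, target)
  switch(spec$family,
    mse = mse_loss(pred, target),
    charbonnier = charbonnier_loss(pred, target, spec$eps),
    compound = {
      ch <- charbonnier_loss(pred, target, spec$eps)
      if (spec$lambda == 0) return(ch)
      if (is.null(extractor))
        extractor <- perceptual_extractor(spec$extractor,
                                          num_scales = spec$num_scales)
      ch + spec$lambda * perceptual_loss(pred, target, extractor, spec$eps)
    })
}
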