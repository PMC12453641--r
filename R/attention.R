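# Windowed multi-head self-attention with shifted windows, relative position
# bias, channel attention (CCAFL / plain CAL) and the combined attention
# transformer unit (CATU).
#
# Feature maps: exported functions accept either an H x W matrix or a
# C x H x W array; internally everything is an N x C matrix with positions
# in column-major order (p = r + (c-1)*H).

## ---- layout helpers -----------------------------------------------------

fm_to_mat <- function(x) {
  if (is.matrix(x)) {
    list(m = matrix(as.vector(x), ncol = 1L), C = 1L,
         H = nrow(x), W = ncol(x), was_matrix = TRUE)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    list(m = t(matrix(x, d[1L], d[2L] * d[3L])), C = d[1L],
         H = d[2L], W = d[3L], was_matrix = FALSE)
  } else {
    stop("feature must be an H x W matrix or a C x H x W array",
         call. = FALSE)
  }
}

mat_to_fm <- function(m, H, W, was_matrix = FALSE) {
  if (was_matrix && ncol(m) == 1L) return(matrix(m[, 1L], H, W))
  array(t(m), c(ncol(m), H, W))
}

check_finite_fm <- function(x, what = "feature") {
  if (length(x) == 0L || any(!is.finite(x)))
    stop(what, " must be non-empty with all values finite", call. = FALSE)
  invisible(NULL)
}

## ---- window geometry ----------------------------------------------------

# Window-order gather index: padded Hp x Wp feature -> rows ordered
# window-by-window (window grid column-major, positions within each window
# column-major).
win_index <- function(Hp, Wp, M) {
  key <- paste("win", Hp, Wp, M, sep = "_")
  idx <- .ad$cache[[key]]
  if (!is.null(idx)) return(idx)
  nwh <- Hp %/% M
  nww <- Wp %/% M
  idx <- integer(Hp * Wp)
  pos <- 1L
  within_r <- rep(seq_len(M), M)
  within_c <- rep(seq_len(M), each = M)
  for (wj in seq_len(nww)) {
    for (wi in seq_len(nwh)) {
      r <- (wi - 1L) * M + within_r
      c <- (wj - 1L) * M + within_c
      idx[pos:(pos + M * M - 1L)] <- r + (c - 1L) * Hp
      pos <- pos + M * M
    }
  }
  .ad$cache[[key]] <- idx
  idx
}

# Cyclic roll by -offset on both axes (the shifted-window shift).
shift_index <- function(H, W, offset) {
  key <- paste("shf", H, W, offset, sep = "_")
  idx <- .ad$cache[[key]]
  if (!is.null(idx)) return(idx)
  r <- ((seq_len(H) - 1L + offset) %% H) + 1L
  c <- ((seq_len(W) - 1L + offset) %% W) + 1L
  idx <- as.integer(outer(r, (c - 1L) * H, "+"))
  .ad$cache[[key]] <- idx
  idx
}

# Relative position index (M^2 x M^2) into a (2M-1)^2 bias table.
rel_pos_index <- function(M) {
  key <- paste("rpi", M, sep = "_")
  idx <- .ad$cache[[key]]
  if (!is.null(idx)) return(idx)
  r <- rep(seq_len(M), M)
  c <- rep(seq_len(M), each = M)
  dr <- outer(r, r, "-") + M        # 1 .. 2M-1
  dc <- outer(c, c, "-") + M
  idx <- matrix(as.integer(dr + (dc - 1L) * (2L * M - 1L)), M * M, M * M)
  .ad$cache[[key]] <- idx
  idx
}

# Additive attention masks for shifted windows: -100 on pairs of positions
# that originate from different image regions after the cyclic shift.
swin_masks <- function(Hp, Wp, M, s) {
  key <- paste("msk", Hp, Wp, M, s, sep = "_")
  mm <- .ad$cache[[key]]
  if (!is.null(mm)) return(mm)
  slice_id <- function(n) {
    id <- integer(n)
    id[seq_len(max(n - M, 0L))] <- 0L
    if (n - M + 1L <= n - s) id[(n - M + 1L):(n - s)] <- 1L
    id[(n - s + 1L):n] <- 2L
    id
  }
  rid <- slice_id(Hp)
  cid <- slice_id(Wp)
  region <- outer(rid, 3L * cid, "+")
  wi <- win_index(Hp, Wp, M)
  reg_w <- region[wi]
  nw <- (Hp * Wp) %/% (M * M)
  m2 <- M * M
  mm <- vector("list", nw)
  for (w in seq_len(nw)) {
    ids <- reg_w[(w - 1L) * m2 + seq_len(m2)]
    mk <- matrix(0, m2, m2)
    mk[outer(ids, ids, "!=")] <- -100
    mm[[w]] <- mk
  }
  .ad$cache[[key]] <- mm
  mm
}

# Reflect padding index to reach a target length, folding as often as the
# source length requires (so any size can be padded to any multiple).
fold_reflect_idx <- function(n, target) {
  if (target == n) return(seq_len(n))
  extra <- target - n
  lo <- extra %/% 2L
  hi <- extra - lo
  pos <- seq.int(1L - lo, n + hi)
  if (n == 1L) return(rep(1L, target))
  per <- 2L * (n - 1L)
  x <- (pos - 1L) %% per
  x[x >= n] <- per - x[x >= n]
  as.integer(x + 1L)
}

pad_to_multiple_idx <- function(H, W, mult) {
  Hp <- as.integer(ceiling(H / mult) * mult)
  Wp <- as.integer(ceiling(W / mult) * mult)
  ri <- fold_reflect_idx(H, Hp)
  ci <- fold_reflect_idx(W, Wp)
  # which padded rows hold the original image (for exact cropping)
  extra_h <- Hp - H; lo_h <- extra_h %/% 2L
  extra_w <- Wp - W; lo_w <- extra_w %/% 2L
  orig_r <- lo_h + seq_len(H)
  orig_c <- lo_w + seq_len(W)
  crop <- as.integer(outer(orig_r, (orig_c - 1L) * Hp, "+"))
  list(idx = as.integer(outer(ri, (ci - 1L) * H, "+")),
       Hp = Hp, Wp = Wp, crop = crop)
}

## ---- parameter constructors --------------------------------------------

trunc_normal <- function(n, std = 0.02) {
  x <- stats::rnorm(n, 0, std)
  pmin(pmax(x, -2 * std), 2 * std)
}

mk_w <- function(nr, nc, std = 0.02) {
  ad_param(matrix(trunc_normal(nr * nc, std), nr, nc))
}

mk_b <- function(n) ad_param(numeric(n))

#' Construct windowed self-attention parameters
#'
#' Creates the query/key/value projection matrices, the output projection,
#' and the zero-initialised relative position bias table covering all
#' (2M-1)^2 relative offsets, for multi-head attention inside M x M windows.
#'
#' @param C channel count (must be divisible by `num_heads`).
#' @param M window side length.
#' @param num_heads number of attention heads; default one head per 32
#'   channels (at least one).
#' @param std standard deviation of the truncated-normal projection init.
#' @return a list of parameters usable with [window_attention()].
#' @export
attention_params <- function(C, M, num_heads = max(1L, C %/% 32L),
                             std = 0.02) {
  if (C %% num_heads != 0L)
    stop("C must be divisible by num_heads", call. = FALSE)
  list(
    wq = mk_w(C, C, std), bq = mk_b(C),
    wk = mk_w(C, C, std), bk = mk_b(C),
    wv = mk_w(C, C, std), bv = mk_b(C),
    proj_w = mk_w(C, C, std), proj_b = mk_b(C),
    bias = ad_param(matrix(0, (2L * M - 1L)^2, num_heads)),
    num_heads = as.integer(num_heads), M = as.integer(M), C = as.integer(C)
  )
}

new_bn_stats <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- numeric(C)
  e$var <- rep(1, C)
  e
}

#' Construct channel-attention parameters (CCAFL or plain CAL)
#'
#' The gate consists of two 3x3 convolutions (the first reducing channels to
#' one third, the second restoring them), two global-average-pool paths each
#' with its own 1x1 convolution and feature normalisation, a ReLU fusion, and
#' a final 1x1 convolution with sigmoid producing per-channel weights in
#' (0, 1).  In the `ccafl` variant the first pooling path sees the reduced
#' activation output; in the `cal` variant both pooling paths see only the
#' last convolution's output (identical layer budget).
#'
#' @param C input channel count (>= 3).
#' @param variant `"ccafl"` or `"cal"`.
#' @param std truncated-normal init standard deviation.
#' @return a parameter list usable with [channel_attention()].
#' @export
channel_attention_params <- function(C, variant = c("ccafl", "cal"),
                                     std = 0.02) {
  variant <- match.arg(variant)
  if (C < 3L) stop("channel attention requires C >= 3", call. = FALSE)
  Cr <- max(1L, as.integer(round(C / 3)))
  poolA_in <- if (variant == "ccafl") Cr else C
  list(
    conv1_w = mk_w(9L * C, Cr, std), conv1_b = mk_b(Cr),
    conv2_w = mk_w(9L * Cr, C, std), conv2_b = mk_b(C),
    poolA_w = mk_w(poolA_in, C, std),
    bnA_g = ad_param(rep(1, C)), bnA_b = mk_b(C), bnA_rs = new_bn_stats(C),
    poolB_w = mk_w(C, C, std),
    bnB_g = ad_param(rep(1, C)), bnB_b = mk_b(C), bnB_rs = new_bn_stats(C),
    final_w = mk_w(C, C, std), final_b = mk_b(C),
    variant = variant, C = as.integer(C), Cr = Cr
  )
}

#' Construct the full parameter set of one combined attention transformer unit
#'
#' Bundles layer norms, (shifted-)window attention, the channel-attention
#' gate and a GELU MLP (expansion ratio 4).
#'
#' @inheritParams attention_params
#' @param use_ca include a channel-attention gate (`"ccafl"`, `"cal"`) or
#'   `"none"`.
#' @param mlp_ratio hidden width of the MLP as a multiple of `C`.
#' @return a nested parameter list usable with [catu_forward()].
#' @export
catu_params <- function(C, M, num_heads = max(1L, C %/% 32L),
                        use_ca = c("ccafl", "cal", "none"), mlp_ratio = 4L,
                        std = 0.02) {
  use_ca <- match.arg(use_ca)
  hid <- as.integer(mlp_ratio * C)
  list(
    ln1_g = ad_param(rep(1, C)), ln1_b = mk_b(C),
    attn = attention_params(C, M, num_heads, std),
    ca = if (use_ca != "none") channel_attention_params(C, use_ca, std) else NULL,
    ln2_g = ad_param(rep(1, C)), ln2_b = mk_b(C),
    mlp_w1 = mk_w(C, hid, std), mlp_b1 = mk_b(hid),
    mlp_w2 = mk_w(hid, C, std), mlp_b2 = mk_b(C)
  )
}

## ---- internal layers (autodiff path) ------------------------------------

# Windowed (optionally shifted) multi-head self-attention on a (B*H*W) x C
# node (B stacked image blocks).  Dims must be multiples of M.
layer_wmsa <- function(x, H, W, p, shifted = FALSE, B = 1L) {
  M <- p$M
  heads <- p$num_heads
  m2 <- M * M
  N <- H * W
  s <- if (shifted) M %/% 2L else 0L
  key <- paste("wfwd", H, W, M, s, B, sep = "_")
  idx <- .ad$cache[[key]]
  if (is.null(idx)) {
    one <- win_index(H, W, M)
    if (s > 0L) one <- shift_index(H, W, s)[one]
    idx <- list(fwd = bat_idx(one, B, N), inv = bat_idx(order(one), B, N))
    .ad$cache[[key]] <- idx
  }
  h <- ad_gather(x, idx$fwd)
  q <- ad_linear(h, p$wq, p$bq)
  k <- ad_linear(h, p$wk, p$bk)
  v <- ad_linear(h, p$wv, p$bv)
  nw <- (B * N) %/% m2
  masks <- if (s > 0L) rep(swin_masks(H, W, M, s), B) else NULL
  o <- ad_wmsa(q, k, v, p$bias, rel_pos_index(M), masks, nw, m2, heads)
  o <- ad_linear(o, p$proj_w, p$proj_b)
  ad_gather(o, idx$inv)   # undo shift-then-partition in one gather
}

# Channel-attention gate on a (B*H*W) x C node; returns gated conv2 output.
layer_channel_attention <- function(x, H, W, p, training = FALSE, B = 1L) {
  a1 <- ad_lrelu(ad_conv2d(x, p$conv1_w, p$conv1_b, H, W, 3L, B = B))
  c2 <- ad_conv2d(a1, p$conv2_w, p$conv2_b, H, W, 3L, B = B)
  inA <- if (p$variant == "ccafl") a1 else c2
  gA <- ad_bnvec(ad_linear(ad_gap_batch(inA, B), p$poolA_w),
                 p$bnA_g, p$bnA_b, p$bnA_rs, training)
  gB <- ad_bnvec(ad_linear(ad_gap_batch(c2, B), p$poolB_w),
                 p$bnB_g, p$bnB_b, p$bnB_rs, training)
  fused <- ad_relu(ad_add(gA, gB))
  wgt <- ad_sigmoid(ad_linear(fused, p$final_w, p$final_b))
  ad_rowscale_batch(c2, wgt, B)
}

# One CATU: pre-norm (S)W-MSA + alpha-scaled channel attention + residual,
# then a pre-norm MLP with residual.
layer_catu <- function(x, H, W, p, alpha = 0.01, shifted = FALSE,
                       training = FALSE, msa_on_raw_input = FALSE, B = 1L) {
  x_ln <- ad_layernorm(x, p$ln1_g, p$ln1_b)
  a_in <- if (msa_on_raw_input) x else x_ln
  att <- layer_wmsa(a_in, H, W, p$attn, shifted, B)
  x1 <- ad_add(att, x)
  if (!is.null(p$ca) && alpha != 0) {
    x1 <- ad_add(x1, ad_scale(layer_channel_attention(x_ln, H, W, p$ca,
                                                      training, B), alpha))
  }
  h <- ad_layernorm(x1, p$ln2_g, p$ln2_b)
  h <- ad_linear(h, p$mlp_w1, p$mlp_b1)
  h <- ad_gelu(h)
  h <- ad_linear(h, p$mlp_w2, p$mlp_b2)
  ad_add(x1, h)
}

## ---- exported operations -------------------------------------------------

#' Partition a feature map into non-overlapping M x M windows
#'
#' Reflect-pads the feature so that `M` divides both spatial dimensions,
#' then splits it into (Hp*Wp)/M^2 windows.  The returned object retains the
#' padding metadata, so [window_reverse()] inverts the operation exactly.
#'
#' @param feature an H x W matrix or C x H x W array of finite values.
#' @param M window side length (positive integer).
#' @param shift_offset cyclic-shift offset recorded in the window set
#'   (0 for W-MSA, M/2 for SW-MSA); the shift itself is applied with
#'   [cyclic_shift()] before partitioning.
#' @return an object of class `window_set`: a list with `windows`
#'   (num_windows x M^2 x C array), `window_size`, `source_height`,
#'   `source_width`, `shift_offset` and padding metadata.
#' @examples
#' ws <- window_partition(matrix(rnorm(64), 8, 8), M = 4)
#' dim(ws$windows)  # 4 windows of 16 positions
#' @export
window_partition <- function(feature, M, shift_offset = 0L) {
  if (length(M) != 1L || is.na(M) || M <= 0L || M != round(M))
    stop("M must be a positive integer", call. = FALSE)
  M <- as.integer(M)
  f <- fm_to_mat(feature)
  check_finite_fm(f$m)
  pd <- pad_to_multiple_idx(f$H, f$W, M)
  m <- f$m[pd$idx, , drop = FALSE]
  wi <- win_index(pd$Hp, pd$Wp, M)
  m <- m[wi, , drop = FALSE]
  nw <- (pd$Hp * pd$Wp) %/% (M * M)
  w <- array(0, c(nw, M * M, f$C))
  for (ch in seq_len(f$C)) w[, , ch] <- t(matrix(m[, ch], M * M, nw))
  structure(list(windows = w, window_size = M,
                 source_height = f$H, source_width = f$W,
                 shift_offset = as.integer(shift_offset),
                 padded_height = pd$Hp, padded_width = pd$Wp,
                 was_matrix = f$was_matrix),
            class = "window_set")
}

#' Reassemble a feature map from a window set
#'
#' Exact spatial inverse of [window_partition()]; padding introduced during
#' partitioning is cropped away.
#'
#' @param ws a `window_set` as returned by [window_partition()].
#' @return the original-layout feature (H x W matrix or C x H x W array).
#' @export
window_reverse <- function(ws) {
  if (!inherits(ws, "window_set"))
    stop("ws must be a window_set", call. = FALSE)
  M <- ws$window_size
  d <- dim(ws$windows)
  nw_expect <- (ws$padded_height * ws$padded_width) %/% (M * M)
  if (d[1L] != nw_expect || d[2L] != M * M)
    stop("window_set is internally inconsistent", call. = FALSE)
  C <- d[3L]
  m <- matrix(0, ws$padded_height * ws$padded_width, C)
  wi <- win_index(ws$padded_height, ws$padded_width, M)
  for (ch in seq_len(C)) m[wi, ch] <- as.vector(t(ws$windows[, , ch]))
  pd <- pad_to_multiple_idx(ws$source_height, ws$source_width, M)
  m <- m[pd$crop, , drop = FALSE]
  mat_to_fm(m, ws$source_height, ws$source_width, ws$was_matrix)
}

#' Cyclically shift a feature map
#'
#' Rolls both spatial axes by `-offset` (the shifted-window convention);
#' `cyclic_shift(cyclic_shift(x, o), -o)` is the identity.
#'
#' @param feature an H x W matrix or C x H x W array.
#' @param offset integer shift; 0 is the identity.
#' @return feature of identical shape and layout.
#' @export
cyclic_shift <- function(feature, offset) {
  f <- fm_to_mat(feature)
  idx <- shift_index(f$H, f$W, as.integer(offset))
  mat_to_fm(f$m[idx, , drop = FALSE], f$H, f$W, f$was_matrix)
}

#' Windowed multi-head self-attention over a window set
#'
#' Applies per-window, per-head scaled dot-product attention
#' `SoftMax(Q K' / sqrt(d) + B [+ mask]) V` followed by the output
#' projection, where B is the learnable relative position bias.  Every
#' softmax row sums to one; output shape equals input shape.
#'
#' @param ws a `window_set`.
#' @param params attention parameters from [attention_params()].
#' @param mask optional list of additive M^2 x M^2 mask matrices (one per
#'   window).  If `ws$shift_offset > 0` and `mask` is `NULL`, the standard
#'   shifted-window mask (-100 on cross-region pairs) is constructed
#'   automatically.
#' @param project apply the output projection (default `TRUE`; disable to
#'   inspect the raw attention output).
#' @return a `window_set` of identical shape.
#' @export
window_attention <- function(ws, params, mask = NULL, project = TRUE) {
  if (!inherits(ws, "window_set"))
    stop("ws must be a window_set", call. = FALSE)
  d <- dim(ws$windows)
  C <- d[3L]
  if (C != params$C)
    stop("channel count of window set and params disagree", call. = FALSE)
  M <- ws$window_size
  m2 <- M * M
  nw <- d[1L]
  if (is.null(mask) && ws$shift_offset > 0L)
    mask <- swin_masks(ws$padded_height, ws$padded_width, M, ws$shift_offset)
  # flatten to (nw*m2) x C, window-major
  xm <- matrix(0, nw * m2, C)
  for (ch in seq_len(C)) xm[, ch] <- as.vector(t(ws$windows[, , ch]))
  q <- nd_val(ad_linear(xm, params$wq, params$bq))
  k <- nd_val(ad_linear(xm, params$wk, params$bk))
  v <- nd_val(ad_linear(xm, params$wv, params$bv))
  o <- nd_val(ad_wmsa(q, k, v, params$bias, rel_pos_index(M), mask,
                      nw, m2, params$num_heads))
  if (project) o <- nd_val(ad_linear(o, params$proj_w, params$proj_b))
  out <- ws
  for (ch in seq_len(C)) out$windows[, , ch] <- t(matrix(o[, ch], m2, nw))
  out
}

#' Channel attention gate (CCAFL or plain CAL)
#'
#' Runs the two-convolution stack and the pooled attention gate described in
#' [channel_attention_params()]; the sigmoid channel weights (strictly inside
#' (0, 1)) multiply the last convolution's output.  Spatial dimensions are
#' unchanged.
#'
#' @param feature an H x W matrix or C x H x W array with C >= 3.
#' @param params parameters from [channel_attention_params()].
#' @return feature of identical shape and layout.
#' @export
channel_attention <- function(feature, params) {
  f <- fm_to_mat(feature)
  if (f$C < 3L) stop("channel attention requires C >= 3", call. = FALSE)
  if (f$C != params$C)
    stop("channel count of feature and params disagree", call. = FALSE)
  o <- nd_val(layer_channel_attention(f$m, f$H, f$W, params))
  mat_to_fm(o, f$H, f$W, f$was_matrix)
}

#' Combined attention transformer unit forward pass
#'
#' Computes the pre-norm transformer block with an added alpha-scaled
#' channel-attention term:
#' `X1 = (S)W-MSA(LN(X)) + alpha * CCAFL(LN(X)) + X;
#'  Xout = X1 + MLP(LN(X1))`.
#' Setting `msa_on_raw_input = TRUE` feeds the un-normalised input to the
#' attention branch instead.
#'
#' @param feature an H x W matrix or C x H x W array; spatial dims must be
#'   multiples of the window size in `params$attn$M` (use
#'   [window_partition()]'s padding otherwise).
#' @param params parameters from [catu_params()].
#' @param alpha non-negative scale of the channel-attention branch.
#' @param shifted use SW-MSA (cyclic half-window shift with mask) instead of
#'   W-MSA.  Consecutive units alternate `FALSE`/`TRUE`.
#' @param msa_on_raw_input attention on the raw residual stream rather than
#'   the normalised one.
#' @return feature of identical shape and layout.
#' @export
catu_forward <- function(feature, params, alpha = 0.01, shifted = FALSE,
                         msa_on_raw_input = FALSE) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  f <- fm_to_mat(feature)
  M <- params$attn$M
  if (f$H %% M != 0L || f$W %% M != 0L)
    stop("spatial dims must be multiples of the window size", call. = FALSE)
  o <- nd_val(layer_catu(f$m, f$H, f$W, params, alpha, shifted,
                         training = FALSE,
                         msa_on_raw_input = msa_on_raw_input))
  mat_to_fm(o, f$H, f$W, f$was_matrix)
}
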