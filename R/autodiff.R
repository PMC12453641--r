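# Tape-based reverse-mode automatic differentiation on dense numeric arrays.
#
# Feature maps are stored as N x C matrices (N = H*W spatial positions in
# column-major order, p = r + (c-1)*H); spatial structure is carried
# explicitly by the layer code, not by the tensor.  Each operation records a
# backward closure on an active tape; backward() replays the tape in reverse.
# Parameters are leaf nodes that persist across steps and accumulate
# gradients in-place.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$cache <- new.env(parent = emptyenv())  # index-table cache, keyed by geometry

ad_tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_active <- function() !is.null(.ad$tape)

is_node <- function(x) inherits(x, "ad_node")

nd_val <- function(x) if (is_node(x)) x$v else x

# Leaf parameter node: never on the tape, gradient accumulated in-place.
ad_param <- function(v) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$bk <- NULL
  class(n) <- "ad_node"
  n
}

new_node <- function(v, bk = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$bk <- bk
  class(n) <- "ad_node"
  t <- .ad$tape
  if (!is.null(t) && !is.null(bk)) {
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[t$n]] <- n
  }
  n
}

acc_g <- function(n, g) {
  if (is_node(n)) {
    if (is.null(n$g)) n$g <- g else n$g <- n$g + g
  }
  invisible(NULL)
}

# Run reverse pass from a scalar loss node over the active tape.
ad_backward <- function(loss) {
  stopifnot(is_node(loss), ad_active())
  loss$g <- 1
  t <- .ad$tape
  if (t$n > 0L) {
    for (i in seq.int(t$n, 1L)) {
      n <- t$nodes[[i]]
      if (!is.null(n$g) && !is.null(n$bk)) n$bk(n$g)
    }
  }
  invisible(NULL)
}

rec <- function() !is.null(.ad$tape)

## ---- elementwise / arithmetic ------------------------------------------

ad_add <- function(a, b) {
  v <- nd_val(a) + nd_val(b)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) { acc_g(a, g); acc_g(b, g) })
}

ad_sub <- function(a, b) {
  v <- nd_val(a) - nd_val(b)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) { acc_g(a, g); acc_g(b, -g) })
}

ad_mul <- function(a, b) {
  av <- nd_val(a); bv <- nd_val(b)
  v <- av * bv
  if (!rec()) return(new_node(v))
  new_node(v, function(g) { acc_g(a, g * bv); acc_g(b, g * av) })
}

ad_scale <- function(a, s) {
  v <- nd_val(a) * s
  if (!rec()) return(new_node(v))
  new_node(v, function(g) acc_g(a, g * s))
}

## ---- linear algebra -----------------------------------------------------

ad_matmul <- function(a, b) {
  av <- nd_val(a); bv <- nd_val(b)
  v <- av %*% bv
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    acc_g(a, g %*% t(bv))
    acc_g(b, t(av) %*% g)
  })
}

# X [N x Cin] %*% W [Cin x Cout] + bias [Cout] broadcast over rows.
ad_linear <- function(x, w, b = NULL) {
  xv <- nd_val(x); wv <- nd_val(w)
  v <- xv %*% wv
  if (!is.null(b)) v <- sweep_add_rows(v, nd_val(b))
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    acc_g(x, g %*% t(wv))
    acc_g(w, crossprod(xv, g))
    if (!is.null(b)) acc_g(b, colSums(g))
  })
}

sweep_add_rows <- function(m, b) {
  # add vector b to every row of m without forming an explicit matrix copy
  m + rep(b, each = nrow(m))
}

## ---- indexing / reshaping ----------------------------------------------

# Row gather: out = x[idx, ].  Handles duplicated indices (padding) exactly:
# the adjoint is scatter-add.
ad_gather <- function(x, idx, n_src = NULL) {
  xv <- nd_val(x)
  if (is.null(n_src)) n_src <- nrow(xv)
  v <- xv[idx, , drop = FALSE]
  if (!rec()) return(new_node(v))
  nc <- ncol(xv)
  new_node(v, function(g) {
    rs <- rowsum(g, idx)
    dx <- matrix(0, n_src, nc)
    dx[as.integer(rownames(rs)), ] <- rs
    acc_g(x, dx)
  })
}

ad_cols <- function(x, cols) {
  xv <- nd_val(x)
  v <- xv[, cols, drop = FALSE]
  if (!rec()) return(new_node(v))
  nc <- ncol(xv); nr <- nrow(xv)
  new_node(v, function(g) {
    dx <- matrix(0, nr, nc)
    dx[, cols] <- g
    acc_g(x, dx)
  })
}

ad_cbind <- function(a, b) {
  av <- nd_val(a); bv <- nd_val(b)
  v <- cbind(av, bv)
  if (!rec()) return(new_node(v))
  na <- ncol(av)
  new_node(v, function(g) {
    acc_g(a, g[, seq_len(na), drop = FALSE])
    acc_g(b, g[, -seq_len(na), drop = FALSE])
  })
}

## ---- activations --------------------------------------------------------

ad_relu <- function(x) {
  xv <- nd_val(x)
  v <- pmax(xv, 0)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) acc_g(x, g * (xv > 0)))
}

ad_lrelu <- function(x, slope = 0.01) {
  xv <- nd_val(x)
  v <- ifelse(xv > 0, xv, slope * xv)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) acc_g(x, g * ifelse(xv > 0, 1, slope)))
}

# GELU, tanh approximation (cheap closed-form derivative)
ad_gelu <- function(x) {
  xv <- nd_val(x)
  k <- sqrt(2 / pi)
  u <- k * (xv + 0.044715 * xv^3)
  th <- tanh(u)
  v <- 0.5 * xv * (1 + th)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    du <- k * (1 + 3 * 0.044715 * xv^2)
    acc_g(x, g * (0.5 * (1 + th) + 0.5 * xv * (1 - th^2) * du))
  })
}

ad_sigmoid <- function(x) {
  xv <- nd_val(x)
  v <- stats::plogis(xv)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) acc_g(x, g * v * (1 - v)))
}

## ---- normalization ------------------------------------------------------

# Layer normalization over the channel axis (each row of the N x C matrix),
# with learnable per-channel gain/shift.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- nd_val(x); gv <- nd_val(gamma); bv <- nd_val(beta)
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep_add_rows(xhat * rep(gv, each = nrow(xv)), bv)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    acc_g(gamma, colSums(g * xhat))
    acc_g(beta, colSums(g))
    dxhat <- g * rep(gv, each = nrow(g))
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    acc_g(x, inv * (dxhat - m1 - xhat * m2))
  })
}

# Feature normalization with running statistics (used on pooled channel
# vectors inside the channel-attention gate).  Statistics are treated as
# constants in the backward pass; during training they are updated in-place
# by exponential moving average on the environment `rs`.
ad_bnvec <- function(x, gamma, beta, rs, training = FALSE,
                     momentum = 0.1, eps = 1e-5) {
  xv <- nd_val(x)  # [1 x C]
  if (training) {
    delta <- colMeans(xv) - rs$mean
    spread <- colMeans((xv - rep(rs$mean, each = nrow(xv)))^2)
    rs$var <- (1 - momentum) * rs$var + momentum * pmax(spread, delta^2)
    rs$mean <- rs$mean + momentum * delta
  }
  inv <- 1 / sqrt(rs$var + eps)
  xhat <- (xv - rep(rs$mean, each = nrow(xv))) * rep(inv, each = nrow(xv))
  gv <- nd_val(gamma); bv <- nd_val(beta)
  v <- sweep_add_rows(xhat * rep(gv, each = nrow(xv)), bv)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    acc_g(gamma, colSums(g * xhat))
    acc_g(beta, colSums(g))
    acc_g(x, g * rep(gv * inv, each = nrow(g)))
  })
}

## ---- reductions ---------------------------------------------------------

ad_colmeans <- function(x) {
  xv <- nd_val(x)
  nr <- nrow(xv)
  v <- matrix(colMeans(xv), 1L)
  if (!rec()) return(new_node(v))
  new_node(v, function(g) acc_g(x, matrix(rep(g / nr, each = nr), nr)))
}

# Per-image global average pool over a row-blocked batch:
# x is [B*N x C] with image blocks stacked; returns [B x C].
ad_gap_batch <- function(x, B) {
  xv <- nd_val(x)
  N <- nrow(xv) %/% B
  grp <- rep.int(seq_len(B), rep.int(N, B))
  v <- rowsum(xv, grp, reorder = FALSE) / N
  if (!rec()) return(new_node(v))
  new_node(v, function(g) acc_g(x, g[grp, , drop = FALSE] / N))
}

# Per-image channel scaling: w is [B x C], each image's rows scaled by its
# own weight row.
ad_rowscale_batch <- function(x, w, B) {
  xv <- nd_val(x); wv <- nd_val(w)
  N <- nrow(xv) %/% B
  grp <- rep.int(seq_len(B), rep.int(N, B))
  wm <- wv[grp, , drop = FALSE]
  v <- xv * wm
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    acc_g(x, g * wm)
    acc_g(w, rowsum(g * xv, grp, reorder = FALSE))
  })
}

ad_mean_all <- function(x) {
  xv <- nd_val(x)
  v <- mean(xv)
  if (!rec()) return(new_node(v))
  n <- length(xv); dm <- dim(xv)
  new_node(v, function(g) {
    d <- array(g / n, if (is.null(dm)) n else dm)
    acc_g(x, d)
  })
}

# Multiply every row of X [N x C] by the channel weight row w [1 x C].
ad_rowscale <- function(x, w) {
  xv <- nd_val(x); wv <- nd_val(w)
  nr <- nrow(xv)
  wm <- rep(as.vector(wv), each = nr)
  v <- xv * wm
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    acc_g(x, g * wm)
    acc_g(w, matrix(colSums(g * xv), 1L))
  })
}

## ---- losses (fused) -----------------------------------------------------

ad_charbonnier <- function(pred, target, eps = 1e-3) {
  pv <- nd_val(pred); tv <- nd_val(target)
  d <- pv - tv
  s <- sqrt(d * d + eps * eps)
  v <- mean(s)
  if (!rec()) return(new_node(v))
  n <- length(d)
  new_node(v, function(g) {
    dd <- g * d / s / n
    acc_g(pred, dd)
    acc_g(target, -dd)
  })
}

ad_mse <- function(pred, target) {
  pv <- nd_val(pred); tv <- nd_val(target)
  d <- pv - tv
  v <- mean(d * d)
  if (!rec()) return(new_node(v))
  n <- length(d)
  new_node(v, function(g) {
    dd <- g * 2 * d / n
    acc_g(pred, dd)
    acc_g(target, -dd)
  })
}

## ---- convolution --------------------------------------------------------

# Reflect-padding index for a 1-D axis of length n padded by p on both sides.
reflect_idx <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  if (n == 1L) return(rep(1L, n + 2L * p))
  base <- c(seq.int(p + 1L, 2L, -1L), seq_len(n), seq.int(n - 1L, n - p))
  # reflect without repeating the edge sample; fold indices that overshoot
  base[base < 1L] <- 2L - base[base < 1L]
  base[base > n] <- 2L * n - base[base > n]
  base
}

# Replicate a row-index vector across B image blocks of N rows each.
bat_idx <- function(idx, B, N) {
  if (B == 1L) return(idx)
  as.integer(rep.int(idx, B) +
               rep.int((seq_len(B) - 1L) * N, rep.int(length(idx), B)))
}

# Cached geometry tables for conv2d: padded-source row gather + im2col map.
conv_tables <- function(H, W, kh, kw, stride, pad, B = 1L) {
  keyb <- paste("cv", H, W, kh, kw, stride, pad, B, sep = "_")
  tbb <- .ad$cache[[keyb]]
  if (!is.null(tbb)) return(tbb)
  base <- conv_tables_1(H, W, kh, kw, stride, pad)
  if (B == 1L) return(base)
  npos <- base$npos
  Sm <- matrix(base$S, npos, base$k2)
  Sb <- Sm[rep.int(seq_len(npos), B), , drop = FALSE] +
    rep.int((seq_len(B) - 1L) * (H * W), rep.int(npos, B))
  tbb <- list(S = as.integer(Sb), npos = B * npos,
              Ho = base$Ho, Wo = base$Wo, k2 = base$k2)
  .ad$cache[[keyb]] <- tbb
  tbb
}

conv_tables_1 <- function(H, W, kh, kw, stride, pad) {
  key <- paste("cv", H, W, kh, kw, stride, pad, sep = "_")
  tb <- .ad$cache[[key]]
  if (!is.null(tb)) return(tb)
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  ri <- reflect_idx(H, ph)
  ci <- reflect_idx(W, pw)
  Hp <- length(ri); Wp <- length(ci)
  # padded position -> source position (column-major over H x W)
  pidx <- as.integer(outer(ri, (ci - 1L) * H, "+"))
  or <- seq.int(1L, Hp - kh + 1L, stride)
  oc <- seq.int(1L, Wp - kw + 1L, stride)
  Ho <- length(or); Wo <- length(oc)
  npos <- Ho * Wo
  # top-left padded index of each output position (column-major Ho x Wo)
  tl <- as.integer(outer(or, (oc - 1L) * Hp, "+"))
  # per kernel element offset in padded coordinates
  off <- as.integer(outer(0L:(kh - 1L), (0L:(kw - 1L)) * Hp, "+"))
  # S[p, q] = source index feeding output position p through kernel elem q
  S <- matrix(0L, npos, kh * kw)
  for (q in seq_len(kh * kw)) S[, q] <- pidx[tl + off[q]]
  tb <- list(S = as.vector(S), npos = npos, Ho = Ho, Wo = Wo, k2 = kh * kw)
  .ad$cache[[key]] <- tb
  tb
}

# 2-D convolution on an N x Cin feature matrix with spatial dims (H, W).
# Weight is stored as a [kh*kw*Cin x Cout] matrix (kernel element fastest,
# then input channel).  Reflect padding keeps "same" output size at stride 1.
ad_conv2d <- function(x, w, b, H, W, kh = 3L, kw = kh, stride = 1L,
                      B = 1L) {
  xv <- nd_val(x); wv <- nd_val(w)
  cin <- ncol(xv)
  tb <- conv_tables(H, W, kh, kw, stride, "reflect", B)
  cols <- xv[tb$S, , drop = FALSE]
  dim(cols) <- c(tb$npos, tb$k2 * cin)
  v <- cols %*% wv
  if (!is.null(b)) v <- sweep_add_rows(v, nd_val(b))
  out <- if (!rec()) new_node(v) else {
    nsrc <- nrow(xv)
    new_node(v, function(g) {
      acc_g(w, crossprod(cols, g))
      if (!is.null(b)) acc_g(b, colSums(g))
      if (is_node(x)) {
        dcols <- g %*% t(wv)
        dim(dcols) <- c(tb$npos * tb$k2, cin)
        rs <- rowsum(dcols, tb$S)
        dx <- matrix(0, nsrc, cin)
        dx[as.integer(rownames(rs)), ] <- rs
        acc_g(x, dx)
      }
    })
  }
  attr(out, "Ho") <- tb$Ho
  attr(out, "Wo") <- tb$Wo
  out
}

# 2x2 stride-2 transposed convolution: per-position linear map Cin -> 4*Cout
# followed by exact depth-to-space.  Doubles H and W.
ad_deconv2 <- function(x, w, b, H, W, B = 1L) {
  xv <- nd_val(x); wv <- nd_val(w)
  cout <- ncol(wv) %/% 4L
  y2 <- xv %*% wv
  if (!is.null(b)) y2 <- sweep_add_rows(y2, rep(nd_val(b), 4L))
  key <- paste("d2s", H, W, B, sep = "_")
  tb <- .ad$cache[[key]]
  if (is.null(tb)) {
    H2 <- 2L * H; W2 <- 2L * W
    r2 <- rep(seq_len(H2), W2)
    c2 <- rep(seq_len(W2), each = H2)
    sr <- (r2 + 1L) %/% 2L
    sc <- (c2 + 1L) %/% 2L
    grp <- (1L - r2 %% 2L) + 2L * (1L - c2 %% 2L) + 1L  # row parity fastest
    src <- sr + (sc - 1L) * H
    rp <- cbind(bat_idx(src, B, H * W), rep.int(grp, B))
    tb <- list(rp = rp, nout = B * H2 * W2)
    .ad$cache[[key]] <- tb
  }
  v <- matrix(0, tb$nout, cout)
  for (gi in 1:4) {
    sel <- tb$rp[, 2L] == gi
    v[sel, ] <- y2[tb$rp[sel, 1L], (gi - 1L) * cout + seq_len(cout), drop = FALSE]
  }
  if (!rec()) return(new_node(v))
  new_node(v, function(g) {
    dy2 <- matrix(0, nrow(xv), 4L * cout)
    for (gi in 1:4) {
      sel <- tb$rp[, 2L] == gi
      dy2[tb$rp[sel, 1L], (gi - 1L) * cout + seq_len(cout)] <-
        g[sel, , drop = FALSE]
    }
    acc_g(w, crossprod(xv, dy2))
    if (!is.null(b)) {
      db4 <- colSums(dy2)
      acc_g(b, db4[seq_len(cout)] + db4[cout + seq_len(cout)] +
              db4[2L * cout + seq_len(cout)] + db4[3L * cout + seq_len(cout)])
    }
    if (is_node(x)) acc_g(x, dy2 %*% t(wv))
  })
}

# Fixed 2x bilinear upsampling (half-pixel centers); exact linear adjoint.
ad_bilinear_up2 <- function(x, H, W, B = 1L) {
  xv <- nd_val(x)
  key <- paste("bl2", H, W, B, sep = "_")
  tb <- .ad$cache[[key]]
  if (is.null(tb)) {
    H2 <- 2L * H; W2 <- 2L * W
    coord <- function(n, i) {  # input coordinate of output sample i (1-based)
      s <- (i - 0.5) / 2 + 0.5
      s0 <- floor(s)
      fr <- s - s0
      s0c <- pmin(pmax(s0, 1), n)
      s1c <- pmin(pmax(s0 + 1, 1), n)
      list(lo = as.integer(s0c), hi = as.integer(s1c), f = fr)
    }
    rr <- coord(H, seq_len(2L * H))
    cc <- coord(W, seq_len(2L * W))
    r2 <- rep(seq_len(H2), W2); c2 <- rep(seq_len(W2), each = H2)
    i00 <- rr$lo[r2] + (cc$lo[c2] - 1L) * H
    i10 <- rr$hi[r2] + (cc$lo[c2] - 1L) * H
    i01 <- rr$lo[r2] + (cc$hi[c2] - 1L) * H
    i11 <- rr$hi[r2] + (cc$hi[c2] - 1L) * H
    fr <- rr$f[r2]; fc <- cc$f[c2]
    idx1 <- cbind(bat_idx(i00, B, H * W), bat_idx(i10, B, H * W),
                  bat_idx(i01, B, H * W), bat_idx(i11, B, H * W))
    w1 <- cbind((1 - fr) * (1 - fc), fr * (1 - fc),
                (1 - fr) * fc, fr * fc)
    tb <- list(idx = idx1,
               w = w1[rep.int(seq_len(nrow(w1)), B), , drop = FALSE])
    .ad$cache[[key]] <- tb
  }
  v <- xv[tb$idx[, 1L], , drop = FALSE] * tb$w[, 1L] +
       xv[tb$idx[, 2L], , drop = FALSE] * tb$w[, 2L] +
       xv[tb$idx[, 3L], , drop = FALSE] * tb$w[, 3L] +
       xv[tb$idx[, 4L], , drop = FALSE] * tb$w[, 4L]
  if (!rec()) return(new_node(v))
  nsrc <- nrow(xv)
  new_node(v, function(g) {
    dx <- matrix(0, nsrc, ncol(g))
    for (k in 1:4) {
      rs <- rowsum(g * tb$w[, k], tb$idx[, k])
      ii <- as.integer(rownames(rs))
      dx[ii, ] <- dx[ii, ] + rs
    }
    acc_g(x, dx)
  })
}

## ---- windowed multi-head self-attention (fused) -------------------------

# q, k, v: [nw*m2 x C] nodes ordered window-by-window; bias: relative
# position bias table node [(2M-1)^2 x heads]; ridx: m2 x m2 integer matrix
# into the bias table; masks: NULL or list of m2 x m2 additive matrices per
# window.  Scaled dot-product attention per window and head; softmax rows
# sum to one by construction.
ad_wmsa <- function(q, k, v, bias, ridx, masks, nw, m2, heads) {
  qv <- nd_val(q); kv <- nd_val(k); vv <- nd_val(v)
  bt <- nd_val(bias)
  C <- ncol(qv)
  dh <- C %/% heads
  sc <- 1 / sqrt(dh)
  out <- matrix(0, nw * m2, C)
  keepA <- rec()
  Astore <- if (keepA) vector("list", nw * heads) else NULL
  bmats <- lapply(seq_len(heads), function(h) matrix(bt[ridx, h], m2, m2))
  for (w in seq_len(nw)) {
    rows <- (w - 1L) * m2 + seq_len(m2)
    mk <- if (is.null(masks)) NULL else masks[[w]]
    for (h in seq_len(heads)) {
      cidx <- (h - 1L) * dh + seq_len(dh)
      Q <- qv[rows, cidx, drop = FALSE]
      K <- kv[rows, cidx, drop = FALSE]
      V <- vv[rows, cidx, drop = FALSE]
      S <- tcrossprod(Q, K) * sc + bmats[[h]]
      if (!is.null(mk)) S <- S + mk
      S <- S - max(S)        # global shift suffices for softmax stability
      A <- exp(S)
      A <- A / rowSums(A)
      out[rows, cidx] <- A %*% V
      if (keepA) Astore[[(w - 1L) * heads + h]] <- A
    }
  }
  if (!rec()) return(new_node(out))
  new_node(out, function(g) {
    dq <- matrix(0, nrow(qv), C)
    dk <- matrix(0, nrow(qv), C)
    dv <- matrix(0, nrow(qv), C)
    dbt <- matrix(0, nrow(bt), heads)
    rvec <- as.vector(ridx)
    for (w in seq_len(nw)) {
      rows <- (w - 1L) * m2 + seq_len(m2)
      for (h in seq_len(heads)) {
        cidx <- (h - 1L) * dh + seq_len(dh)
        A <- Astore[[(w - 1L) * heads + h]]
        Q <- qv[rows, cidx, drop = FALSE]
        K <- kv[rows, cidx, drop = FALSE]
        V <- vv[rows, cidx, drop = FALSE]
        gO <- g[rows, cidx, drop = FALSE]
        dv[rows, cidx] <- dv[rows, cidx] + crossprod(A, gO)
        dA <- tcrossprod(gO, V)
        dS <- A * (dA - rowSums(dA * A))
        rsb <- rowsum(as.vector(dS), rvec)
        ii <- as.integer(rownames(rsb))
        dbt[ii, h] <- dbt[ii, h] + rsb
        dq[rows, cidx] <- dq[rows, cidx] + (dS %*% K) * sc
        dk[rows, cidx] <- dk[rows, cidx] + crossprod(dS, Q) * sc
      }
    }
    acc_g(q, dq); acc_g(k, dk); acc_g(v, dv); acc_g(bias, dbt)
  })
}

## ---- parameter utilities -------------------------------------------------

# Flatten a nested (possibly unnamed) list-of-nodes into a named flat list.
flatten_params <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  for (i in seq_along(p)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    full <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    el <- p[[i]]
    if (is_node(el)) {
      out[[full]] <- el
    } else if (is.list(el)) {
      out <- c(out, flatten_params(el, full))
    }
  }
  out
}

zero_grads <- function(params) {
  for (p in flatten_params(params)) p$g <- NULL
  invisible(NULL)
}
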