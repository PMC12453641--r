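# Window machinery, attention semantics, channel attention and the CATU.

test_that("window partitioning yields HW/M^2 windows and inverts exactly", {
  set.seed(1)
  x8 <- matrix(rnorm(64), 8, 8)
  ws <- window_partition(x8, 4L)
  expect_equal(dim(ws$windows), c(4L, 16L, 1L))
  expect_identical(window_reverse(ws), x8)

  x64 <- array(rnorm(3 * 64 * 64), c(3, 64, 64))
  ws64 <- window_partition(x64, 8L)
  expect_equal(dim(ws64$windows)[1], 64L)
  expect_identical(window_reverse(ws64), x64)

  # non-divisible size: padded, then restored exactly
  x10 <- matrix(rnorm(100), 10, 10)
  ws10 <- window_partition(x10, 4L)
  expect_equal(dim(ws10$windows)[1], 9L)  # padded to 12x12
  expect_identical(window_reverse(ws10), x10)

  # single window covering the whole feature
  x16 <- matrix(rnorm(256), 16, 16)
  expect_identical(window_reverse(window_partition(x16, 16L)), x16)

  expect_error(window_partition(x8, 0L), "positive integer")
  expect_error(window_partition(matrix(numeric(0), 0, 0), 4L), "finite")
})

test_that("cyclic shift rolls both axes and round-trips exactly", {
  x <- matrix(seq_len(16), 4, 4)
  expect_identical(cyclic_shift(x, 0L), x)
  s <- cyclic_shift(x, 2L)
  # rolled by -offset: new[r, c] = old[r + 2 mod 4, c + 2 mod 4]
  idx <- function(i) ((i - 1L + 2L) %% 4L) + 1L
  for (r in 1:4) for (c in 1:4)
    expect_identical(s[r, c], x[idx(r), idx(c)])
  expect_identical(cyclic_shift(s, -2L), x)
})

test_that("attention semantics: uniform weights, masking, row normalization", {
  set.seed(2)
  C <- 8L
  ap <- attention_params(C, 4L, num_heads = 2L)
  ap$wq$v[] <- 0; ap$bq$v[] <- 0
  ap$wk$v[] <- 0; ap$bk$v[] <- 0
  x <- array(rnorm(C * 8 * 8), c(C, 8, 8))
  ws <- window_partition(x, 4L)
  out <- window_attention(ws, ap, project = FALSE)
  # zero Q/K and zero bias: softmax of zeros is uniform, so each output
  # position is the window mean of the value projection
  for (w in 1:4) {
    vals <- ws$windows[w, , ] %*% ap$wv$v +
      matrix(ap$bv$v, 16, C, byrow = TRUE)
    mu <- colMeans(vals)
    for (p in 1:16) expect_equal(out$windows[w, p, ], mu, tolerance = 1e-12)
  }

  # masked positions receive zero attention weight: mask out position 1
  mask1 <- matrix(0, 16, 16); mask1[, 1] <- -1e9
  masks <- replicate(4, mask1, simplify = FALSE)
  out_m <- window_attention(ws, ap, mask = masks, project = FALSE)
  for (w in 1:4) {
    vals <- ws$windows[w, , ] %*% ap$wv$v +
      matrix(ap$bv$v, 16, C, byrow = TRUE)
    mu_wo1 <- colMeans(vals[-1, , drop = FALSE])   # uniform over the rest
    expect_equal(out_m$windows[w, 2, ], mu_wo1, tolerance = 1e-9)
  }
})

test_that("single-window attention equals dense global self-attention", {
  for (seed in 1:6) {
    set.seed(seed)
    C <- 16L
    x <- array(rnorm(C * 8 * 8), c(C, 8, 8))
    ap <- attention_params(C, 8L, num_heads = 2L)
    ap$bias$v[] <- rnorm(length(ap$bias$v), sd = 0.05)
    got <- window_attention(window_partition(x, 8L), ap, project = FALSE)
    # brute-force O(N^2) dense attention over all 64 positions
    Xw <- t(matrix(x, C, 64))
    Q <- Xw %*% ap$wq$v + matrix(ap$bq$v, 64, C, byrow = TRUE)
    K <- Xw %*% ap$wk$v + matrix(ap$bk$v, 64, C, byrow = TRUE)
    V <- Xw %*% ap$wv$v + matrix(ap$bv$v, 64, C, byrow = TRUE)
    ridx <- hf$rel_pos_index(8L)
    for (h in 1:2) {
      ci <- (h - 1) * 8 + 1:8
      S <- Q[, ci] %*% t(K[, ci]) / sqrt(8) +
        matrix(ap$bias$v[ridx, h], 64, 64)
      A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
      expect_true(all(abs(rowSums(A) - 1) < 1e-6))
      ref <- A %*% V[, ci]
      expect_equal(got$windows[1, , ci], ref, tolerance = 1e-5)
    }
  }
})

test_that("unmasked unshifted attention has no cross-window leakage", {
  set.seed(3)
  C <- 8L
  ap <- attention_params(C, 4L, num_heads = 1L)
  x <- array(rnorm(C * 8 * 8), c(C, 8, 8))
  ws <- window_partition(x, 4L)
  out <- window_attention(ws, ap)
  perm <- c(3L, 1L, 4L, 2L)
  wsp <- ws
  wsp$windows <- ws$windows[perm, , , drop = FALSE]
  outp <- window_attention(wsp, ap)
  expect_equal(outp$windows, out$windows[perm, , , drop = FALSE],
               tolerance = 1e-12)
})

test_that("channel attention weights are sigmoid-bounded and reduce channels by one third", {
  set.seed(4)
  C <- 9L
  cp <- channel_attention_params(C, "ccafl")
  expect_equal(cp$Cr, 3L)
  x <- array(rnorm(C * 8 * 8, sd = 3), c(C, 8, 8))
  out <- channel_attention(x, cp)
  expect_equal(dim(out), dim(x))
  # recompute the gate weights and check they lie strictly inside (0, 1)
  f <- hf$fm_to_mat(x)
  a1 <- hf$nd_val(hf$ad_lrelu(hf$ad_conv2d(f$m, cp$conv1_w, cp$conv1_b,
                                           8L, 8L, 3L)))
  c2 <- hf$nd_val(hf$ad_conv2d(a1, cp$conv2_w, cp$conv2_b, 8L, 8L, 3L))
  gate <- t(matrix(out, C, 64)) / c2
  expect_true(all(gate > 0 & gate < 1))
  expect_error(channel_attention(array(rnorm(2 * 64), c(2, 8, 8)),
                                 channel_attention_params(3L)), "C >= 3")
})

test_that("constant input with zero gate weights yields 0.5 channel weights", {
  C <- 6L
  cp <- channel_attention_params(C, "ccafl")
  cp$final_w$v[] <- 0; cp$final_b$v[] <- 0
  x <- array(1, c(C, 8, 8))
  out <- channel_attention(x, cp)
  f <- hf$fm_to_mat(x)
  a1 <- hf$nd_val(hf$ad_lrelu(hf$ad_conv2d(f$m, cp$conv1_w, cp$conv1_b,
                                           8L, 8L, 3L)))
  c2 <- hf$nd_val(hf$ad_conv2d(a1, cp$conv2_w, cp$conv2_b, 8L, 8L, 3L))
  expect_equal(out, hf$mat_to_fm(0.5 * c2, 8L, 8L, FALSE),
               tolerance = 1e-12)
})

test_that("CCAFL and CAL agree exactly when the first pooling path is zeroed", {
  set.seed(5)
  C <- 6L
  ccafl <- channel_attention_params(C, "ccafl")
  cal <- channel_attention_params(C, "cal")
  # identical conv stack and shared-path weights
  for (nm in c("conv1_w", "conv1_b", "conv2_w", "conv2_b", "poolB_w",
               "bnB_g", "bnB_b", "final_w", "final_b"))
    cal[[nm]]$v <- ccafl[[nm]]$v
  ccafl$poolA_w$v[] <- 0; ccafl$bnA_b$v[] <- 0
  cal$poolA_w$v[] <- 0; cal$bnA_b$v[] <- 0
  x <- array(rnorm(C * 64), c(C, 8, 8))
  expect_equal(channel_attention(x, ccafl), channel_attention(x, cal),
               tolerance = 1e-14)
})

test_that("CATU reduces to the identity with zero projections and alpha = 0", {
  set.seed(6)
  C <- 8L
  cp <- catu_params(C, 4L, num_heads = 1L, use_ca = "ccafl")
  cp$attn$proj_w$v[] <- 0; cp$attn$proj_b$v[] <- 0
  cp$mlp_w2$v[] <- 0; cp$mlp_b2$v[] <- 0
  x <- array(rnorm(C * 64), c(C, 8, 8))
  expect_equal(catu_forward(x, cp, alpha = 0), x, tolerance = 1e-14)
  # shifted variant too
  expect_equal(catu_forward(x, cp, alpha = 0, shifted = TRUE), x,
               tolerance = 1e-14)
})

test_that("channel-attention contribution scales linearly with alpha", {
  set.seed(7)
  C <- 8L
  cp <- catu_params(C, 4L, num_heads = 1L, use_ca = "ccafl")
  cp$mlp_w2$v[] <- 0; cp$mlp_b2$v[] <- 0  # isolate the first residual sum
  x <- array(rnorm(C * 64), c(C, 8, 8))
  y0 <- catu_forward(x, cp, alpha = 0)
  ca_out <- channel_attention(hf$mat_to_fm(
    hf$nd_val(hf$ad_layernorm(hf$fm_to_mat(x)$m, cp$ln1_g, cp$ln1_b)),
    8L, 8L, FALSE), cp$ca)
  for (a in c(0.01, 0.1)) {
    ya <- catu_forward(x, cp, alpha = a)
    expect_equal(ya - y0, a * ca_out, tolerance = 1e-10)
    expect_lte(max(abs(ya - y0)), a * max(abs(ca_out)) + 1e-12)
  }
})
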