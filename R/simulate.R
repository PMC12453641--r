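# Synthetic paired low-dose / normal-dose CT data: piecewise-smooth
# anatomy-like ellipse phantoms, a parallel-beam projector with
# dose-dependent Poisson counting noise and ramp-filtered back-projection
# (yielding the correlated streak/quantum noise of real low-dose CT), and
# paired patch sampling for training.

# Fixture constants of the simulator (frozen):
#  - mu_per_pixel converts phantom intensity (0..1) to attenuation per
#    traversed pixel, giving body-scale total attenuation around 2-3.
#  - n_angles: parallel-beam views over 180 degrees.
#  - electronic_sigma: Gaussian noise floor on pre-log detector counts.
#  - default_I0: incident photon count chosen once so that the baseline
#    PSNR(ndct, ldct) of 64x64 phantoms falls in the upper-teens dB band
#    typical of quarter-dose CT inputs.
ldct_constants <- function() {
  list(mu_per_pixel = 0.05, n_angles = 180L, electronic_sigma = 2.0,
       default_I0 = 200)
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

## ---- phantoms ------------------------------------------------------------

#' Generate an anatomy-like ellipse phantom
#'
#' Builds a piecewise-smooth phantom in [0, 1]: a soft-tissue body outline
#' (the first ellipse), interior structures of varied contrast, and — when
#' `num_ellipses >= 2` — one low-contrast lesion-like ellipse that exercises
#' edge preservation.  Bit-exactly reproducible from `(spec, seed)`.
#'
#' @param height,width image dimensions (>= 32).
#' @param num_ellipses total number of ellipses, body outline included.
#' @param seed integer seed.
#' @return an object of class `ct_phantom`: list with `image` (H x W matrix
#'   in [0, 1]), `ellipses` (data.frame of centre, axes, angle, intensity),
#'   and `seed`.
#' @export
generate_phantom <- function(height = 64L, width = height,
                             num_ellipses = 8L, seed = 1L) {
  if (height < 32L || width < 32L)
    stop("phantom dimensions must be at least 32", call. = FALSE)
  if (num_ellipses < 1L)
    stop("num_ellipses must be >= 1", call. = FALSE)
  local_seed(seed, {
    es <- data.frame(cx = width / 2, cy = height / 2,
                     a = 0.42 * width, b = 0.45 * height,
                     angle = 0, intensity = 0.35)
    n_extra <- num_ellipses - 1L
    if (n_extra > 0L) {
      for (i in seq_len(n_extra)) {
        lesion <- (i == n_extra)   # last interior ellipse is low-contrast
        a <- stats::runif(1, 0.05, if (lesion) 0.10 else 0.22) * width
        b <- stats::runif(1, 0.05, if (lesion) 0.10 else 0.22) * height
        # keep the structure inside the body outline
        cx <- width / 2 + stats::runif(1, -0.25, 0.25) * width
        cy <- height / 2 + stats::runif(1, -0.25, 0.25) * height
        val <- if (lesion) 0.04 else
          sample(c(-1, 1), 1) * stats::runif(1, 0.08, 0.45)
        es <- rbind(es, data.frame(cx = cx, cy = cy, a = a, b = b,
                                   angle = stats::runif(1, 0, pi),
                                   intensity = val))
      }
    }
    img <- matrix(0, height, width)
    xg <- matrix(rep(seq_len(width), each = height), height)
    yg <- matrix(rep(seq_len(height), width), height)
    for (j in seq_len(nrow(es))) {
      e <- es[j, ]
      dx <- xg - e$cx; dy <- yg - e$cy
      u <- (dx * cos(e$angle) + dy * sin(e$angle)) / e$a
      v <- (-dx * sin(e$angle) + dy * cos(e$angle)) / e$b
      img <- img + e$intensity * (u * u + v * v <= 1)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, ellipses = es, seed = as.integer(seed),
                   height = as.integer(height), width = as.integer(width)),
              class = "ct_phantom")
  })
}

## ---- parallel-beam projection and FBP -----------------------------------

# Fast bilinear sampling with zero outside the support (one-pixel zero pad
# makes edge interpolation exact).
bilinear_sample <- function(imgp, Hp, Wp, xs, ys) {
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 < Wp & y0 >= 1 & y0 < Hp
  z <- numeric(length(xs))
  xi <- x0[ok]; yi <- y0[ok]; fxi <- fx[ok]; fyi <- fy[ok]
  i00 <- yi + (xi - 1) * Hp
  z[ok] <- (1 - fxi) * ((1 - fyi) * imgp[i00] + fyi * imgp[i00 + 1]) +
           fxi * ((1 - fyi) * imgp[i00 + Hp] + fyi * imgp[i00 + Hp + 1])
  z
}

#' Parallel-beam forward projection
#'
#' Line integrals of `img` over `n_angles` views spanning 180 degrees, with
#' max(H, W) detector bins at unit (pixel) spacing.
#'
#' @param img numeric matrix.
#' @param n_angles number of projection angles.
#' @return sinogram matrix (detector bins x angles).
#' @export
radon_transform <- function(img, n_angles = 180L) {
  H <- nrow(img); W <- ncol(img)
  n <- max(H, W)
  Hp <- H + 2L; Wp <- W + 2L
  imgp <- matrix(0, Hp, Wp)
  imgp[2:(H + 1L), 2:(W + 1L)] <- img
  cx <- (W + 1) / 2 + 1; cy <- (H + 1) / 2 + 1   # centre in padded coords
  t <- seq_len(n) - (n + 1) / 2          # detector coordinates
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles
  sino <- matrix(0, n, n_angles)
  tp <- rep(t, times = n)                 # detector index varies fastest
  sp <- rep(t, each = n)                  # integration samples along the ray
  for (k in seq_len(n_angles)) {
    th <- angles[k]
    xs <- cx + tp * cos(th) - sp * sin(th)
    ys <- cy + tp * sin(th) + sp * cos(th)
    z <- bilinear_sample(imgp, Hp, Wp, xs, ys)
    sino[, k] <- rowSums(matrix(z, n, n))
  }
  sino
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filtered back-projection (discrete Ram-Lak kernel, linear detector
#' interpolation) of a parallel-beam sinogram produced by
#' [radon_transform()].
#'
#' @param sino sinogram (detector bins x angles).
#' @param H,W output image dimensions.
#' @return reconstructed H x W matrix.
#' @export
fbp_reconstruct <- function(sino, H = nrow(sino), W = H) {
  n <- nrow(sino)
  n_angles <- ncol(sino)
  npad <- 2L^ceiling(log2(2L * n))
  # discrete ramp filter built from its real-space kernel (avoids the DC
  # bias of the naive |f| discretisation)
  kern <- numeric(npad)
  kern[1] <- 0.25
  odd <- seq.int(1L, npad %/% 2L, 2L)
  kern[odd + 1L] <- -1 / (pi * odd)^2
  kern[npad - odd + 1L] <- -1 / (pi * odd)^2
  ramp <- 2 * Re(stats::fft(kern))
  filt <- matrix(0, npad, n_angles)
  filt[seq_len(n), ] <- sino
  for (k in seq_len(n_angles)) {
    filt[, k] <- Re(stats::fft(stats::fft(filt[, k]) * ramp,
                               inverse = TRUE)) / npad
  }
  q <- filt[seq_len(n), , drop = FALSE]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xg <- rep(seq_len(W), each = H) - cx
  yg <- rep(seq_len(H), times = W) - cy
  t0 <- (n + 1) / 2
  rec <- numeric(H * W)
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles
  for (k in seq_len(n_angles)) {
    th <- angles[k]
    tt <- xg * cos(th) + yg * sin(th) + t0
    rec <- rec + stats::approx(seq_len(n), q[, k], xout = tt, rule = 2)$y
  }
  matrix(rec * pi / (2 * n_angles), H, W)
}

## ---- dose simulation -----------------------------------------------------

rpois_large <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e7
  if (any(big))
    out[big] <- stats::rnorm(sum(big), lambda[big], sqrt(lambda[big]))
  if (any(!big))
    out[!big] <- stats::rpois(sum(!big), lambda[!big])
  out
}

#' Simulate a low-dose acquisition of a normal-dose slice
#'
#' In `"sinogram_poisson"` mode the slice is forward-projected
#' (parallel-beam, 180 views over 180 degrees), detector counts
#' `I0 * exp(-line integral)` are Poisson-thinned with a small Gaussian
#' electronic noise floor, log-transformed, and reconstructed by
#' ramp-filtered back-projection — producing the spatially correlated
#' streak/quantum noise characteristic of real low-dose CT.  In
#' `"image_mixed"` mode a fast image-domain surrogate (signal-dependent
#' Poisson plus Gaussian) is used instead.  Noise variance decreases
#' strictly with `I0`.
#'
#' @param ndct normal-dose slice: an H x W matrix in [0, 1] or a
#'   `ct_phantom`.
#' @param I0 incident photon count per detector bin (> 0); smaller is
#'   noisier.  The default is the frozen quarter-dose-like setting.
#' @param mode `"sinogram_poisson"` or `"image_mixed"`.
#' @param seed integer seed; the same seed reproduces the pair bit-exactly.
#' @return an object of class `dose_pair`: list with `ndct`, `ldct`,
#'   `I0`, `mode`, `seed`.
#' @export
simulate_low_dose <- function(ndct, I0 = ldct_constants()$default_I0,
                              mode = c("sinogram_poisson", "image_mixed"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(ndct, "ct_phantom")) ndct <- ndct$image
  if (!is.matrix(ndct)) stop("ndct must be a matrix", call. = FALSE)
  if (!is.numeric(I0) || length(I0) != 1L || I0 <= 0)
    stop("I0 must be a positive number", call. = FALSE)
  kc <- ldct_constants()
  ldct <- local_seed(seed, {
    if (mode == "sinogram_poisson") {
      n <- max(dim(ndct))
      mu <- kc$mu_per_pixel
      L <- radon_transform(ndct, kc$n_angles) * mu
      counts <- I0 * exp(-L)
      noisy <- rpois_large(counts) +
        stats::rnorm(length(counts), 0, kc$electronic_sigma)
      noisy <- pmax(noisy, 0.1)
      Lhat <- -log(noisy / I0)
      dim(Lhat) <- dim(L)
      fbp_reconstruct(Lhat, nrow(ndct), ncol(ndct)) / mu
    } else {
      cp <- I0 / 100
      quantum <- rpois_large(pmax(ndct, 0) * cp) / cp - pmax(ndct, 0)
      ndct + quantum + stats::rnorm(length(ndct), 0, 2 / sqrt(I0))
    }
  })
  structure(list(ndct = ndct, ldct = ldct, I0 = I0, mode = mode,
                 seed = as.integer(seed)), class = "dose_pair")
}

#' Generate a paired low-dose/normal-dose dataset
#'
#' Independent phantoms with deterministic per-pair sub-seeds derived from
#' one master seed; regenerating with the same arguments is bit-identical.
#'
#' @param n_pairs number of slice pairs (>= 1).
#' @param height,width slice dimensions.
#' @param I0 incident photon count (see [simulate_low_dose()]).
#' @param seed master seed.
#' @param mode noise simulation mode.
#' @param num_ellipses ellipses per phantom.
#' @return list of `dose_pair` objects.
#' @export
make_paired_dataset <- function(n_pairs, height = 64L, width = height,
                                I0 = ldct_constants()$default_I0, seed = 1L,
                                mode = "sinogram_poisson",
                                num_ellipses = 8L) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  lapply(seq_len(n_pairs), function(i) {
    sub <- (as.integer(seed) + 7919L * i) %% 2147483647L
    ph <- generate_phantom(height, width, num_ellipses, seed = sub)
    simulate_low_dose(ph, I0 = I0, mode = mode, seed = sub + 1L)
  })
}

#' Split pairs into train/validation/test subsets
#'
#' Deterministic contiguous split by the given ratios (remainders go to the
#' training set).
#'
#' @param pairs list of `dose_pair`s.
#' @param ratios length-3 positive weights, e.g. `c(8, 1, 1)`.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_pairs <- function(pairs, ratios = c(8, 1, 1)) {
  n <- length(pairs)
  n_val <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  n_train <- n - n_val - n_test
  list(train = pairs[seq_len(n_train)],
       val = if (n_val > 0) pairs[n_train + seq_len(n_val)] else list(),
       test = if (n_test > 0) pairs[n_train + n_val + seq_len(n_test)]
              else list())
}

#' Sample paired training patches from a dose pair
#'
#' Random crops at identical coordinates in the low-dose and normal-dose
#' slice, with optional flip/rotation augmentation applied identically to
#' both.  Deterministic given `seed`.
#'
#' @param pair a `dose_pair`.
#' @param patch_size side length of the square patches.
#' @param n_patches number of patches.
#' @param seed integer seed.
#' @param augment apply a random combination of horizontal/vertical flips
#'   and 90-degree rotation to each patch.
#' @return list of lists with `ndct`, `ldct` (patch matrices), `row`,
#'   `col` (top-left crop coordinates).
#' @export
sample_patches <- function(pair, patch_size = 64L, n_patches = 1L,
                           seed = 1L, augment = FALSE) {
  H <- nrow(pair$ndct); W <- ncol(pair$ndct)
  if (patch_size > min(H, W))
    stop("patch_size exceeds image dimensions", call. = FALSE)
  local_seed(seed, {
    lapply(seq_len(n_patches), function(i) {
      r0 <- sample.int(H - patch_size + 1L, 1L)
      c0 <- sample.int(W - patch_size + 1L, 1L)
      rows <- r0 + seq_len(patch_size) - 1L
      cols <- c0 + seq_len(patch_size) - 1L
      nd <- pair$ndct[rows, cols]
      ld <- pair$ldct[rows, cols]
      if (augment) {
        if (stats::runif(1) < 0.5) { nd <- nd[patch_size:1, ]; ld <- ld[patch_size:1, ] }
        if (stats::runif(1) < 0.5) { nd <- nd[, patch_size:1]; ld <- ld[, patch_size:1] }
        if (stats::runif(1) < 0.5) { nd <- t(nd); ld <- t(ld) }
      }
      list(ndct = nd, ldct = ld, row = r0, col = c0)
    })
  })
}
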