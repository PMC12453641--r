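# Full-reference image quality metrics: PSNR, SSIM (Gaussian-weighted,
# 11 x 11, sigma 1.5), and FSIM (log-Gabor phase congruency + Scharr
# gradient similarity), plus per-set aggregation.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`.  Identical images (MSE = 0) are
#' reported as `Inf`.
#'
#' @param ref,test numeric matrices of identical shape.
#' @param data_range dynamic range of the data (default 255, the
#'   display-windowed 8-bit-equivalent scale).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(16, 8, 8), matrix(0, 8, 8))  # 20*log10(255/16)
#' @export
psnr <- function(ref, test, data_range = 255) {
  check_same_shape(ref, test)
  if (data_range <= 0) stop("data_range must be > 0", call. = FALSE)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) %/% 2L
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D correlation along rows (vertical axis), 'same' size.
filt1_col <- function(x, k, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- if (pad == "zero") {
    rbind(matrix(0, r, W), x, matrix(0, r, W))
  } else {
    rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(H, r), , drop = FALSE])
  }
  out <- matrix(0, H, W)
  for (j in seq_along(k))
    out <- out + k[j] * xp[j:(j + H - 1L), , drop = FALSE]
  out
}

# Separable 'same' 2-D filtering (zero padding; callers crop borders).
filt2_sep <- function(x, k) {
  t(filt1_col(t(filt1_col(x, k)), k))
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian window (size 11, sigma 1.5) and the
#' standard stabilizers C1 = (0.01 r)^2, C2 = (0.03 r)^2 where r is the data
#' range.  Border pixels whose window leaves the image are excluded from the
#' mean.
#'
#' @param ref,test numeric matrices of identical shape, at least 11 x 11.
#' @param data_range dynamic range of the data.
#' @param win_size Gaussian window size (odd).
#' @param sigma Gaussian window standard deviation.
#' @return SSIM value (1 for identical images).
#' @export
ssim <- function(ref, test, data_range = 255, win_size = 11L, sigma = 1.5) {
  check_same_shape(ref, test)
  if (min(dim(ref)) < win_size)
    stop("image smaller than the SSIM window", call. = FALSE)
  k <- gaussian_kernel1d(win_size, sigma)
  ux <- filt2_sep(ref, k);  uy <- filt2_sep(test, k)
  uxx <- filt2_sep(ref * ref, k)
  uyy <- filt2_sep(test * test, k)
  uxy <- filt2_sep(ref * test, k)
  vx <- uxx - ux * ux
  vy <- uyy - uy * uy
  vxy <- uxy - ux * uy
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  pad <- (win_size - 1L) %/% 2L
  mean(S[(pad + 1L):(nrow(S) - pad), (pad + 1L):(ncol(S) - pad)])
}

## ---- phase congruency (log-Gabor, 4 scales x 4 orientations) ------------

lowpass_filter <- function(H, W, cutoff = 0.45, n = 15) {
  fx <- fft_freqs(W); fy <- fft_freqs(H)
  r <- sqrt(outer(fy^2, fx^2, "+"))
  1 / (1 + (r / cutoff)^(2 * n))
}

fft_freqs <- function(n) {
  if (n %% 2L == 0L) c(0:(n / 2 - 1), -(n / 2):-1) / n
  else c(0:((n - 1) / 2), -((n - 1) / 2):-1) / n
}

pc_filters <- function(H, W, nscale = 4L, norient = 4L,
                       min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                       d_theta_sigma = 1.2) {
  key <- paste("pcf", H, W, sep = "_")
  ff <- .ad$cache[[key]]
  if (!is.null(ff)) return(ff)
  fx <- fft_freqs(W); fy <- fft_freqs(H)
  radius <- sqrt(outer(fy^2, fx^2, "+"))
  radius[1, 1] <- 1
  theta <- outer(-fy, rep(1, W)) |> atan2(outer(rep(1, H), fx))
  lp <- lowpass_filter(H, W)
  logGabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    fo <- 1 / (min_wavelength * mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2)) * lp
    lg[1, 1] <- 0
    logGabor[[s]] <- lg
  }
  spread <- vector("list", norient)
  theta_sigma <- pi / norient / d_theta_sigma
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sin(theta) * cos(angl) - cos(theta) * sin(angl)
    dc <- cos(theta) * cos(angl) + sin(theta) * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread[[o]] <- exp(-dtheta^2 / (2 * theta_sigma^2))
  }
  ff <- list(logGabor = logGabor, spread = spread, nscale = nscale,
             norient = norient, mult = mult)
  .ad$cache[[key]] <- ff
  ff
}

# 2-D phase congruency map (the PC_2D measure: orientation-summed local
# energy over summed filter amplitude, with a per-orientation noise
# threshold estimated from the finest-scale amplitude).
phase_congruency <- function(x, k_noise = 2.0) {
  H <- nrow(x); W <- ncol(x)
  ff <- pc_filters(H, W)
  X <- stats::fft(x)
  eps <- 1e-4
  energy_sum <- matrix(0, H, W)
  amp_sum <- matrix(0, H, W)
  for (o in seq_len(ff$norient)) {
    sumE <- matrix(0, H, W); sumO <- matrix(0, H, W)
    sumA <- matrix(0, H, W)
    eo <- vector("list", ff$nscale)
    for (s in seq_len(ff$nscale)) {
      filt <- ff$logGabor[[s]] * ff$spread[[o]]
      r <- stats::fft(X * filt, inverse = TRUE) / (H * W)
      eo[[s]] <- r
      sumE <- sumE + Re(r)
      sumO <- sumO + Im(r)
      sumA <- sumA + Mod(r)
      if (s == 1L) tau <- stats::median(Mod(r)) / sqrt(log(4))
    }
    xen <- sqrt(sumE^2 + sumO^2) + eps
    mE <- sumE / xen; mO <- sumO / xen
    energy <- matrix(0, H, W)
    for (s in seq_len(ff$nscale)) {
      e <- Re(eo[[s]]); od <- Im(eo[[s]])
      energy <- energy + e * mE + od * mO - abs(e * mO - od * mE)
    }
    total_tau <- tau * (1 - (1 / ff$mult)^ff$nscale) / (1 - 1 / ff$mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    T <- noise_mean + k_noise * noise_sigma
    energy_sum <- energy_sum + pmax(energy - T, 0)
    amp_sum <- amp_sum + sumA
  }
  energy_sum / (amp_sum + eps)
}

scharr_gradient <- function(x) {
  sm <- c(3, 10, 3) / 16
  df <- c(1, 0, -1)
  p <- "replicate"   # keeps the map exactly shift-invariant at borders
  dx <- t(filt1_col(t(filt1_col(x, sm, p)), df, p))   # horizontal derivative
  dy <- filt1_col(t(filt1_col(t(x), sm, p)), df, p)   # vertical derivative
  sqrt(dx^2 + dy^2)
}

#' Feature similarity index
#'
#' Combines phase-congruency similarity (log-Gabor, 4 scales x 4
#' orientations) and Scharr gradient-magnitude similarity, weighted by the
#' maximum phase congruency, with the standard stabilizers T1 = 0.85 and
#' T2 = 160 (defined on a 0-255 intensity scale; inputs are rescaled to that
#' scale via `data_range`).
#'
#' @param ref,test numeric grayscale matrices of identical shape.
#' @param data_range dynamic range of the inputs.
#' @return FSIM value in (0, 1]; 1 for identical images.
#' @export
fsim <- function(ref, test, data_range = 255) {
  check_same_shape(ref, test)
  T1 <- 0.85; T2 <- 160
  sc <- 255 / data_range
  r <- ref * sc; t_ <- test * sc
  pc1 <- phase_congruency(r)
  pc2 <- phase_congruency(t_)
  g1 <- scharr_gradient(r)
  g2 <- scharr_gradient(t_)
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

## ---- aggregation ---------------------------------------------------------

#' Evaluate a set of reference/test image pairs
#'
#' Computes PSNR, SSIM and FSIM per pair and their arithmetic means; rows
#' are ordered deterministically by `image_id`.
#'
#' @param pairs a list; each element is a list with `ref` and `test`
#'   matrices and optionally `id`.
#' @param data_range dynamic range shared by all images.
#' @return an object of class `metric_report`: list with `per_image`
#'   (data.frame: image_id, psnr, ssim, fsim), `aggregate` (named means)
#'   and `data_range`.
#' @export
evaluate_pairs <- function(pairs, data_range = 255) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("pairs must be a non-empty list", call. = FALSE)
  ids <- vapply(seq_along(pairs), function(i) {
    id <- pairs[[i]]$id
    if (is.null(id)) sprintf("image_%03d", i) else as.character(id)
  }, "")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(image_id = ids[i],
               psnr = psnr(p$ref, p$test, data_range),
               ssim = ssim(p$ref, p$test, data_range),
               fsim = fsim(p$ref, p$test, data_range),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per <- per[order(per$image_id), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(per_image = per,
                 aggregate = c(psnr = mean(per$psnr), ssim = mean(per$ssim),
                               fsim = mean(per$fsim)),
                 data_range = data_range),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Image quality report (", nrow(x$per_image), " image",
      if (nrow(x$per_image) != 1L) "s", ", data range ",
      x$data_range, ")\n", sep = "")
  print(x$per_image, digits = 4)
  cat(sprintf("mean: PSNR %.4f dB, SSIM %.4f, FSIM %.4f\n",
              x$aggregate["psnr"], x$aggregate["ssim"],
              x$aggregate["fsim"]))
  invisible(x)
}

#' Write a metric report to CSV and/or JSON
#'
#' @param report a `metric_report`.
#' @param csv,json optional output paths.
#' @return the report, invisibly.
#' @export
write_metric_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(report$per_image, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(per_image = report$per_image,
                              aggregate = as.list(report$aggregate),
                              data_range = report$data_range),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
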