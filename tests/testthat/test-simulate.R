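# Phantoms, projection/reconstruction, dose-dependent noise, and patch
# sampling.

test_that("phantoms are deterministic, clipped and anatomically structured", {
  p1 <- generate_phantom(48, 48, 6, seed = 3)
  p2 <- generate_phantom(48, 48, 6, seed = 3)
  expect_identical(p1$image, p2$image)
  expect_true(all(p1$image >= 0 & p1$image <= 1))
  expect_gte(nrow(p1$ellipses), 2L)        # body plus interior structure
  expect_error(generate_phantom(16, 48), "at least 32")
  expect_error(generate_phantom(48, 48, 0), "num_ellipses")
})

test_that("a single ellipse covers the analytic area up to rasterization error", {
  p <- generate_phantom(64, 64, 1, seed = 9)
  e <- p$ellipses[1, ]
  area_pix <- sum(p$image > 0)
  area_true <- pi * e$a * e$b
  expect_lt(abs(area_pix - area_true) / area_true, 0.05)
})

test_that("projector conserves mass and FBP inverts it to within discretisation error", {
  fx <- fixture_phantom()
  sino <- radon_transform(fx$ph$image)
  expect_equal(sum(sino[, 1]), sum(fx$ph$image), tolerance = 1e-8)
  expect_equal(sum(sino[, 91]), sum(fx$ph$image), tolerance = 1e-8)
  rmse <- sqrt(mean((fx$clean_rec - fx$ph$image)^2))
  expect_lt(rmse, 0.06)
})

test_that("the noise-free dose limit reproduces the clean reconstruction", {
  fx <- fixture_phantom()
  p <- simulate_low_dose(fx$ph, I0 = 1e12, seed = 4)
  expect_lt(max(abs(p$ldct - fx$clean_rec)), 0.05)
  expect_gt(psnr(fx$ph$image, p$ldct, data_range = 1), 25)
  expect_error(simulate_low_dose(fx$ph, I0 = -1), "positive")
})

test_that("halving the dose increases noise variance (both modes)", {
  fx <- fixture_phantom()
  for (mode in c("sinogram_poisson", "image_mixed")) {
    v <- vapply(c(400, 200), function(I0) {
      mean(vapply(1:6, function(s) {
        p <- simulate_low_dose(fx$ph, I0 = I0, mode = mode, seed = s)
        ref <- if (mode == "sinogram_poisson") fx$clean_rec else
          fx$ph$image
        var(as.vector(p$ldct - ref))
      }, 0))
    }, 0)
    expect_gt(v[2], v[1])
  }
})

test_that("simulated pairs are reproducible and shaped consistently", {
  fx <- fixture_phantom()
  a <- simulate_low_dose(fx$ph, I0 = 300, seed = 12)
  b <- simulate_low_dose(fx$ph, I0 = 300, seed = 12)
  expect_identical(a$ldct, b$ldct)
  expect_identical(dim(a$ldct), dim(a$ndct))
})

test_that("dataset generation is seed-stable with pairwise-distinct phantoms", {
  ds1 <- make_paired_dataset(3, 48, 48, I0 = 300, seed = 77,
                             mode = "image_mixed")
  ds2 <- make_paired_dataset(3, 48, 48, I0 = 300, seed = 77,
                             mode = "image_mixed")
  for (i in 1:3) {
    expect_identical(ds1[[i]]$ndct, ds2[[i]]$ndct)
    expect_identical(ds1[[i]]$ldct, ds2[[i]]$ldct)
  }
  hashes <- vapply(ds1, function(p)
    paste(c(range(p$ndct), mean(p$ndct)), collapse = " "), "")
  expect_identical(length(unique(hashes)), 3L)
})

test_that("train/val/test splitting honours the ratios", {
  ds <- replicate(10, list(ndct = matrix(0, 4, 4)), simplify = FALSE)
  sp <- split_pairs(ds, c(8, 1, 1))
  expect_identical(lengths(sp), c(train = 8L, val = 1L, test = 1L))
  sp2 <- split_pairs(ds[1:4], c(2, 1, 1))
  expect_identical(lengths(sp2), c(train = 2L, val = 1L, test = 1L))
})

test_that("patch sampling crops both slices at identical coordinates", {
  fx <- fixture_phantom()
  pr <- simulate_low_dose(fx$ph, I0 = 300, seed = 5, mode = "image_mixed")
  ps1 <- sample_patches(pr, 32L, 4L, seed = 6)
  ps2 <- sample_patches(pr, 32L, 4L, seed = 6)
  for (i in 1:4) {
    p <- ps1[[i]]
    expect_identical(dim(p$ndct), c(32L, 32L))
    expect_identical(p$ndct, ps2[[i]]$ndct)
    rows <- p$row + 0:31; cols <- p$col + 0:31
    expect_identical(p$ldct, pr$ldct[rows, cols])
    expect_identical(p$ndct, pr$ndct[rows, cols])
  }
  # augmentation applies the same transform to both slices
  pa <- sample_patches(pr, 32L, 6L, seed = 7, augment = TRUE)
  for (p in pa) {
    expect_identical(dim(p$ldct), c(32L, 32L))
    # the ndct/ldct relationship survives the shared transform:
    # their difference has the statistics of the crop, not of a mismatch
    expect_lt(mean(abs(p$ldct - p$ndct)), 0.5)
  }
  expect_error(sample_patches(pr, 128L), "exceeds")
})

test_that("sinogram-mode noise is spatially correlated, unlike white noise", {
  fx <- fixture_phantom()
  p <- simulate_low_dose(fx$ph, I0 = 200, seed = 31)
  noise <- p$ldct - fx$clean_rec
  n <- noise[5:44, 5:44]
  n <- n - mean(n)
  lag_r <- cor(as.vector(n[-1, ]), as.vector(n[-40, ]))
  expect_gt(lag_r, 0.1)
  set.seed(31)
  w <- matrix(rnorm(1600), 40, 40)
  lag_w <- cor(as.vector(w[-1, ]), as.vector(w[-40, ]))
  expect_gt(lag_r, lag_w + 0.1)
})
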