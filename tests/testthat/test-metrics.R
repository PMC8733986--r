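# CNR, line profiles, Gaussian FWHM, radial PSD, PSNR, difference images

test_that("CNR equals 10 on exact-moment two-region input under both rules", {
  # material {9,10,11}: mean 10, sd 1; air {-1,0,1}: mean 0, sd 1
  arr <- array(0, c(3, 3, 1))
  arr[1:3] <- c(9, 10, 11); arr[4:6] <- c(-1, 0, 1)
  mat <- array(FALSE, dim(arr)); mat[1:3] <- TRUE
  air <- array(FALSE, dim(arr)); air[4:6] <- TRUE
  r1 <- cnr(arr, mat, air, rule = "rms")
  r2 <- cnr(arr, mat, air, rule = "mean_sd")
  expect_equal(r1$cnr, 10)
  expect_equal(r2$cnr, 10)
  expect_equal(r1$I_mat, 10); expect_equal(r1$sigma_air, 1)
  # the stored moments recompute the ratio
  expect_equal(r1$cnr, abs(r1$I_mat - r1$I_air) /
                 sqrt((r1$sigma_mat^2 + r1$sigma_air^2) / 2))
})

test_that("CNR is invariant under positive affine intensity transforms", {
  set.seed(5)
  arr <- array(stats::rnorm(8^3), c(8, 8, 8))
  mat <- array(FALSE, dim(arr)); mat[1:100] <- TRUE
  air <- array(FALSE, dim(arr)); air[301:400] <- TRUE
  base <- cnr(arr, mat, air)$cnr
  expect_equal(cnr(3.7 * arr + 11, mat, air)$cnr, base)
  expect_error(cnr(arr, mat, mat), "disjoint")
  expect_error(cnr(array(1, dim(arr)), mat, air), "flat")
})

test_that("line profiles sample constants, stripes and diagonals correctly", {
  expect_equal(extract_profile(matrix(2, 20, 20), c(2, 10), c(18, 10))$values,
               rep(2, 17))
  stripes <- matrix(rep(c(1, 1, 1, 1, 0, 0, 0, 0), 5), 40, 40)  # period 8 rows
  pr <- extract_profile(stripes, c(5, 2), c(5, 38))
  sp <- Mod(stats::fft(pr$values - mean(pr$values)))^2
  k <- which.max(sp[2:floor(length(pr$values) / 2)])
  expect_equal(length(pr$values) / k, 8, tolerance = 0.15)
  diag <- extract_profile(matrix(0, 30, 30), c(3, 4), c(23, 19))
  expect_lt(abs(max(diag$positions) - 25), 0.5)  # 3-4-5 triangle, length 25
  expect_error(extract_profile(matrix(0, 5, 5), c(0, 1), c(3, 3)), "inside")
})

test_that("Gaussian FWHM is recovered to 1% on noiseless peaks", {
  px <- 22  # nm per pixel
  for (sigma in c(2, 5, 10, 15, 20)) {
    x <- seq_len(30 * sigma)
    prof <- list(positions = x * px,
                 values = exp(-(x - length(x) / 2)^2 / (2 * sigma^2)) + 0.3,
                 pixel_size = px)
    fit <- fit_peaks(prof, n_peaks = 1)
    expect_true(fit$ok[1])
    truth <- 2 * sqrt(2 * log(2)) * sigma * px
    expect_lt(abs(fit$fwhm[1] - truth) / truth, 0.01)
  }
  # sigma = 10 px at 22 nm pixels: 23.548 px = 518.1 nm
  x <- seq_len(300)
  prof <- list(positions = x * 22,
               values = exp(-(x - 150)^2 / 200), pixel_size = 22)
  expect_equal(fit_peaks(prof, 1)$fwhm[1], 518.1, tolerance = 1e-3)
})

test_that("two well-separated identical peaks fit to equal widths", {
  x <- seq_len(400)
  v <- exp(-(x - 100)^2 / (2 * 36)) + exp(-(x - 300)^2 / (2 * 36))
  fit <- fit_peaks(list(positions = x, values = v, pixel_size = 1), 2)
  expect_equal(nrow(fit), 2)
  expect_true(all(fit$ok))
  expect_lt(abs(fit$fwhm[1] - fit$fwhm[2]) / fit$fwhm[1], 0.01)
  expect_equal(attr(fit, "fwhm_mean"), mean(fit$fwhm))
})

test_that("noisy-peak FWHM is recovered within 5% on average", {
  x <- seq_len(200)
  clean <- exp(-(x - 100)^2 / (2 * 64))    # sigma 8
  truth <- 2 * sqrt(2 * log(2)) * 8
  est <- vapply(1:100, function(s) {
    set.seed(s)
    v <- clean + stats::rnorm(200, 0, 0.05)
    f <- fit_peaks(list(positions = x, values = v, pixel_size = 1), 1)
    if (f$ok[1]) f$fwhm[1] else NA_real_
  }, 0)
  expect_gt(mean(!is.na(est)), 0.9)
  expect_lt(abs(mean(est, na.rm = TRUE) - truth) / truth, 0.05)
})

test_that("radial PSD localises a pure tone and satisfies Parseval", {
  n <- 64
  xy <- seq_len(n) - 1
  tone <- outer(rep(1, n), sin(2 * pi * xy / 8))   # period 8 px
  ps <- psd1d(tone, window = "rect")
  peak_bin <- which.max(ps$power[-1]) + 1          # skip DC
  expect_equal(ps$frequencies[peak_bin], 0.125, tolerance = 1e-9)
  # Parseval with the rectangular window: total power equals the variance
  set.seed(13)
  img <- matrix(stats::rnorm(n * n), n, n)
  ps2 <- psd1d(img, window = "rect")
  v <- mean((img - mean(img))^2)
  expect_equal(ps2$total_power, v, tolerance = 1e-10)
  # pixel size scales the frequency axis
  ps_nm <- psd1d(tone, pixel_size = 22, window = "rect")
  expect_equal(ps_nm$frequencies[peak_bin], 0.125 / 22)
  expect_error(psd1d(matrix(0, 8, 8)), "16")
})

test_that("white noise has a flat radial spectrum", {
  n <- 32
  acc <- 0
  for (s in 1:100) {
    set.seed(s)
    acc <- acc + psd1d(matrix(stats::rnorm(n * n), n, n), window = "rect")$power
  }
  acc <- acc / 100
  mid <- acc[3:(length(acc) - 1)]   # skip DC/lowest bins (few samples)
  expect_lt(stats::sd(mid) / mean(mid), 0.1)
})

test_that("PSNR closed forms and monotonicity under added noise", {
  ref <- array(stats::runif(16^3), c(16, 16, 16))
  ref <- (ref - min(ref)) / diff(range(ref))      # exact unit range
  expect_identical(psnr(ref, ref), Inf)
  expect_equal(psnr(ref + 0.1, ref), 20)          # constant 0.1 error
  for (s in 1:100) {
    set.seed(s)
    e1 <- array(stats::rnorm(16^3, 0, 0.05), c(16, 16, 16))
    e2 <- e1 + array(stats::rnorm(16^3, 0, 0.05), c(16, 16, 16))
    expect_lt(psnr(ref + e2, ref), psnr(ref + e1, ref))
  }
})

test_that("difference reports detect removed structure and ignore noise", {
  gt <- make_phantom(phantom_spec("lattice", 48, seed = 2))
  z <- volume(array(0, dim(gt$data)))
  same <- difference_report(gt, gt, gt)
  expect_equal(same$mean, 0); expect_equal(same$gt_correlation, 0)
  # removing the phantom itself flags structure removal
  removed <- difference_report(gt, z, gt)
  expect_gt(removed$gt_correlation, 0.99)
  # independent noise differences are uncorrelated with the phantom
  cors <- vapply(1:10, function(s) {
    set.seed(s)
    na <- array(stats::rnorm(48^3), dim(gt$data))
    difference_report(na, z, gt)$gt_correlation
  }, 0)
  expect_lt(max(abs(cors)), 0.05)
  expect_error(difference_report(gt, array(0, c(2, 2, 2))), "differ")
})
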