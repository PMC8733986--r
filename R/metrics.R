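#' Contrast-to-noise ratio between a material and an air ROI
#'
#' `CNR = |I_mat - I_air| / D` where `I_mat`, `I_air` are the mean grey
#' values and `sigma_mat`, `sigma_air` the standard deviations inside the
#' two regions of interest. The denominator is
#' `D = sqrt((sigma_mat^2 + sigma_air^2) / 2)` under the default `"rms"`
#' rule or `(sigma_mat + sigma_air) / 2` under `"mean_sd"`; every result
#' records which rule was used. CNR is invariant under affine intensity
#' transforms `v -> a v + b` with `a > 0`.
#'
#' @param vol a [volume()] (or bare numeric array).
#' @param mat_mask,air_mask logical arrays of the volume's shape selecting
#'   the material and air voxels; they must be disjoint and nonempty.
#' @param rule denominator rule, `"rms"` (default) or `"mean_sd"`.
#' @return An object of class `cnr_result`: list with `I_mat`, `I_air`,
#'   `sigma_mat`, `sigma_air`, `cnr`, `denominator_rule`.
#' @export
cnr <- function(vol, mat_mask, air_mask, rule = c("rms", "mean_sd")) {
  rule <- match.arg(rule)
  data <- if (inherits(vol, "txm_volume")) vol$data else vol
  if (!identical(dim(mat_mask), dim(data)) || !identical(dim(air_mask), dim(data)))
    stop("cnr: masks must have the volume's shape")
  if (any(mat_mask & air_mask)) stop("cnr: masks must be disjoint")
  if (!any(mat_mask) || !any(air_mask)) stop("cnr: masks must be nonempty")
  vm <- data[mat_mask]; va <- data[air_mask]
  sm <- stats::sd(vm); sa <- stats::sd(va)
  den <- if (rule == "rms") sqrt((sm^2 + sa^2) / 2) else (sm + sa) / 2
  if (!is.finite(den) || den == 0) stop("cnr: zero denominator (flat ROIs)")
  structure(list(I_mat = mean(vm), I_air = mean(va),
                 sigma_mat = sm, sigma_air = sa,
                 cnr = abs(mean(vm) - mean(va)) / den,
                 denominator_rule = rule),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("CNR = %.3f (%s rule; I_mat %.4g +- %.3g, I_air %.4g +- %.3g)\n",
              x$cnr, x$denominator_rule, x$I_mat, x$sigma_mat,
              x$I_air, x$sigma_air))
  invisible(x)
}

#' Extract a line profile from a slice
#'
#' Grey values are sampled by bilinear interpolation at unit-pixel steps
#' along the segment from `p0` to `p1` (1-based `(x, y)` pixel
#' coordinates).
#'
#' @param img numeric matrix (a 2-D slice; rows = y, cols = x).
#' @param p0,p1 numeric `(x, y)` endpoints, inside the image.
#' @param pixel_size physical length per pixel.
#' @return An object of class `line_profile`: list with `positions`
#'   (length units, uniform unit-pixel spacing), `values`, `pixel_size`.
#' @export
extract_profile <- function(img, p0, p1, pixel_size = 1) {
  stopifnot(is.matrix(img), length(p0) == 2, length(p1) == 2)
  inside <- function(p) all(p >= 1) && p[1] <= ncol(img) && p[2] <= nrow(img)
  if (!inside(p0) || !inside(p1))
    stop("extract_profile: endpoints must lie inside the image")
  len <- sqrt(sum((p1 - p0)^2))
  s <- seq(0, len, by = 1)
  xs <- p0[1] + (p1[1] - p0[1]) * s / max(len, .Machine$double.eps)
  ys <- p0[2] + (p1[2] - p0[2]) * s / max(len, .Machine$double.eps)
  x0 <- pmin(floor(xs), ncol(img) - 1); y0 <- pmin(floor(ys), nrow(img) - 1)
  fx <- xs - x0; fy <- ys - y0
  v <- (1 - fy) * ((1 - fx) * img[cbind(y0, x0)] + fx * img[cbind(y0, x0 + 1)]) +
       fy * ((1 - fx) * img[cbind(y0 + 1, x0)] + fx * img[cbind(y0 + 1, x0 + 1)])
  structure(list(positions = s * pixel_size, values = as.numeric(v),
                 pixel_size = pixel_size),
            class = "line_profile")
}

# dominant period of a profile in samples, from the periodogram peak
dominant_period <- function(values) {
  n <- length(values)
  sp <- Mod(stats::fft(values - mean(values)))^2
  half <- 2:floor(n / 2 + 1)
  if (!length(half)) return(n)
  kk <- half[which.max(sp[half])] - 1
  n / kk
}

#' Gaussian peak fitting on a line profile
#'
#' Detects the `n_peaks` highest local maxima (enforcing a minimum
#' separation of half the dominant period of the profile) and fits a
#' Gaussian plus constant offset,
#' `A exp(-(x - mu)^2 / (2 sigma^2)) + c0`, to a window around each by
#' Levenberg–Marquardt least squares. The constant offset absorbs the
#' background pedestal that phase-contrast imaging leaves under the peaks.
#' The full width at half maximum is `2 sqrt(2 ln 2) sigma`, reported in
#' the profile's length units. A peak whose fit fails to converge is
#' flagged, not fatal.
#'
#' @param profile a [extract_profile()] result (or a list with `positions`
#'   and `values`), longer than 8 samples.
#' @param n_peaks number of peaks to fit.
#' @param window half-width of the fit window in samples (default: half
#'   the dominant period, at least 4).
#' @return An object of class `peak_fits`: data frame with one row per
#'   peak (`centre`, `sigma`, `amplitude`, `offset`, `fwhm`, `ok`), plus
#'   attributes `fwhm_mean` and `fwhm_sd` over the converged peaks.
#' @export
fit_peaks <- function(profile, n_peaks = 1, window = NULL) {
  pos <- profile$positions; val <- profile$values
  if (length(val) <= 8) stop("fit_peaks: profile must be longer than 8 samples")
  period <- dominant_period(val)
  min_sep <- max(2, round(period / 2))
  if (is.null(window)) window <- max(4, round(period / 2))
  # local maxima
  n <- length(val)
  is_max <- c(FALSE, val[2:(n - 1)] > val[1:(n - 2)] &
                     val[2:(n - 1)] >= val[3:n], FALSE)
  cand <- which(is_max)[order(val[is_max], decreasing = TRUE)]
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) >= n_peaks) break
    if (all(abs(i - picked) >= min_sep)) picked <- c(picked, i)
  }
  if (!length(picked)) stop("fit_peaks: no local maxima found")
  dx <- pos[2] - pos[1]
  rows <- lapply(sort(picked), function(i) {
    idx <- max(1, i - window):min(n, i + window)
    df <- data.frame(x = pos[idx], y = val[idx])
    c0 <- min(df$y)
    start <- list(A = val[i] - c0, mu = pos[i],
                  s = max(dx, window * dx / 4), c0 = c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + c0,
                        data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || coef(fit)["s"] <= 0)
      return(data.frame(centre = pos[i], sigma = NA_real_,
                        amplitude = NA_real_, offset = NA_real_,
                        fwhm = NA_real_, ok = FALSE))
    cf <- coef(fit)
    s <- abs(unname(cf["s"]))
    data.frame(centre = unname(cf["mu"]), sigma = s,
               amplitude = unname(cf["A"]), offset = unname(cf["c0"]),
               fwhm = 2 * sqrt(2 * log(2)) * s, ok = TRUE)
  })
  out <- do.call(rbind, rows)
  ok <- out$fwhm[out$ok]
  attr(out, "fwhm_mean") <- if (length(ok)) mean(ok) else NA_real_
  attr(out, "fwhm_sd") <- if (length(ok) > 1) stats::sd(ok) else NA_real_
  class(out) <- c("peak_fits", "data.frame")
  out
}

#' Radial 1-D power spectral density of a 2-D region
#'
#' Subtracts the mean, applies a separable 2-D window (Hann by default),
#' computes the squared magnitude of the 2-D DFT normalised as
#' `P = |F|^2 / N` (N = number of pixels, so that with the rectangular
#' window `sum(P) / N` equals the image variance — Parseval), and
#' azimuthally averages `P` into radial bins one frequency sample wide.
#'
#' @param roi numeric matrix, at least 16 x 16.
#' @param pixel_size physical length per pixel.
#' @param window `"hann"` (default) or `"rect"`.
#' @return An object of class `psd_curve`: list with `frequencies` (bin
#'   centres, cycles per length unit, 0 to Nyquist), `power`, `window`,
#'   `bin_width`, and `total_power` (`sum(P) / N`; equals the image
#'   variance for the rectangular window).
#' @export
psd1d <- function(roi, pixel_size = 1, window = c("hann", "rect")) {
  window <- match.arg(window)
  if (!is.matrix(roi) || any(dim(roi) < 16))
    stop("psd1d: 'roi' must be a matrix of at least 16 x 16")
  nr <- nrow(roi); nc <- ncol(roi); npix <- nr * nc
  x <- roi - mean(roi)
  if (window == "hann") {
    wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
    wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
    x <- x * outer(wr, wc)
  }
  p2 <- Mod(stats::fft(x))^2 / npix
  fr <- c(seq(0, floor(nr / 2)), -seq(ceiling(nr / 2) - 1, 1)) / nr
  fc <- c(seq(0, floor(nc / 2)), -seq(ceiling(nc / 2) - 1, 1)) / nc
  r <- sqrt(outer(fr^2, fc^2, "+"))
  db <- 1 / min(nr, nc)
  bin <- round(r / db)
  keep <- bin <= floor(0.5 / db)
  pow <- tapply(p2[keep], bin[keep], mean)
  bins <- as.integer(names(pow))
  structure(list(frequencies = bins * db / pixel_size,
                 power = as.numeric(pow), window = window,
                 bin_width = db / pixel_size,
                 total_power = sum(p2) / npix),
            class = "psd_curve")
}

#' Peak signal-to-noise ratio against a reference volume
#'
#' `PSNR = 10 log10(range(ref)^2 / MSE)` in decibels, with `range` the
#' dynamic range of the reference. Identical volumes give `Inf`.
#'
#' @param vol,ref [volume()]s (or numeric arrays) of identical shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(vol, ref) {
  a <- if (inherits(vol, "txm_volume")) vol$data else vol
  b <- if (inherits(ref, "txm_volume")) ref$data else ref
  if (!identical(dim(a), dim(b))) stop("psnr: shapes differ")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(diff(range(b))^2 / mse)
}

#' Difference-image report
#'
#' Computes the voxel-wise difference `a - b` together with its mean and
#' standard deviation. When a ground-truth phantom is supplied, the Pearson
#' correlation of the difference with the ground truth is reported: a
#' denoiser that only removes noise yields a structure-poor difference
#' image with near-zero correlation, whereas removed (or invented)
#' structure shows up as substantial correlation.
#'
#' @param a,b [volume()]s (or arrays) of identical shape (conventionally
#'   the unfiltered input and the filtered output).
#' @param ground_truth optional ground-truth [volume()].
#' @return An object of class `difference_report`: list with `difference`
#'   (array), `mean`, `sd` and `gt_correlation` (`NA` without ground
#'   truth, 0 for a zero difference).
#' @export
difference_report <- function(a, b, ground_truth = NULL) {
  da <- if (inherits(a, "txm_volume")) a$data else a
  db <- if (inherits(b, "txm_volume")) b$data else b
  if (!identical(dim(da), dim(db))) stop("difference_report: shapes differ")
  d <- da - db
  gt_cor <- NA_real_
  if (!is.null(ground_truth)) {
    g <- if (inherits(ground_truth, "txm_volume")) ground_truth$data else ground_truth
    if (!identical(dim(g), dim(d))) stop("difference_report: ground truth shape differs")
    gt_cor <- if (stats::sd(d) == 0 || stats::sd(g) == 0) 0
              else stats::cor(as.vector(d), as.vector(g))
  }
  structure(list(difference = d, mean = mean(d), sd = stats::sd(as.vector(d)),
                 gt_correlation = gt_cor),
            class = "difference_report")
}

#' @export
print.difference_report <- function(x, ...) {
  cat(sprintf("<difference_report> mean %.4g, sd %.4g", x$mean, x$sd))
  if (!is.na(x$gt_correlation))
    cat(sprintf(", correlation with ground truth %.3f", x$gt_correlation))
  cat("\n")
  invisible(x)
}
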