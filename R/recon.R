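#' Reconstruction configuration
#'
#' @param filter_name frequency filter for the sinogram rows:
#'   `"shepp-logan"` (default, ramp windowed by `sinc(f / (2 f_N))`),
#'   `"ramlak"` (pure ramp `|f|`), or `"none"` (no filtering; plain
#'   back-projection).
#' @param pad_factor rows are zero-padded to `pad_factor` times the next
#'   power of two >= detector width before the FFT, which suppresses
#'   circular-convolution wraparound (integer >= 1, default 2).
#' @param circle_mask if `TRUE` (default), voxels outside the circle
#'   inscribed in the reconstruction grid are set to 0.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(filter_name = c("shepp-logan", "ramlak", "none"),
                         pad_factor = 2, circle_mask = TRUE) {
  if (is.character(filter_name) &&
      !all(filter_name %in% c("shepp-logan", "ramlak", "none")))
    stop("recon_config: unknown filter name '",
         setdiff(filter_name, c("shepp-logan", "ramlak", "none"))[1], "'")
  filter_name <- match.arg(filter_name)
  if (!is.numeric(pad_factor) || pad_factor < 1)
    stop("recon_config: 'pad_factor' must be an integer >= 1")
  structure(list(filter_name = filter_name,
                 pad_factor = as.integer(pad_factor),
                 circle_mask = isTRUE(circle_mask)),
            class = "recon_config")
}

# Frequency response of the reconstruction filter on a padded grid of m
# samples. f in cycles/sample; H(f) = 2|f| (Ram-Lak), optionally windowed by
# sinc(f / (2 f_N)) = sin(pi f) / (pi f) with f_N = 0.5 (Shepp-Logan). The
# DC component is 0, so constant rows map to zero.
ramp_response <- function(m, filter_name) {
  f <- c(seq(0, floor(m / 2)), -seq(ceiling(m / 2) - 1, 1)) / m
  h <- 2 * abs(f)
  if (filter_name == "shepp-logan") {
    nz <- f != 0
    h[nz] <- h[nz] * sin(pi * f[nz]) / (pi * f[nz])
  }
  h
}

#' Frequency-domain ramp filtering of a sinogram
#'
#' Each detector row is convolved, via an FFT on a zero-padded grid, with
#' the chosen ramp filter. The DC component is removed, so a constant row
#' filters to zero. With `filter_name = "none"` the input is returned
#' unchanged.
#'
#' @param sino numeric matrix `n_angles x detector_width`
#'   (`detector_width >= 4`).
#' @param cfg a [recon_config()].
#' @return Filtered sinogram of the same shape.
#' @export
filter_sinogram <- function(sino, cfg = recon_config()) {
  if (!inherits(cfg, "recon_config")) stop("filter_sinogram: 'cfg' must be a recon_config")
  if (!is.matrix(sino) || ncol(sino) < 4)
    stop("filter_sinogram: 'sino' must be a matrix with detector width >= 4")
  if (cfg$filter_name == "none") return(sino)
  n <- ncol(sino)
  m <- cfg$pad_factor * 2^ceiling(log2(n))
  h <- ramp_response(m, cfg$filter_name)
  # pad by continuing the edge values (right edge forwards, left edge
  # backwards across the circular wrap): avoids the rect-window ringing of
  # zero padding and maps constant rows exactly to zero
  nr <- ceiling((m - n) / 2); nl <- (m - n) - nr
  padded <- cbind(sino,
                  matrix(sino[, n], nrow(sino), nr),
                  matrix(sino[, 1], nrow(sino), nl))
  ft <- t(stats::mvfft(t(padded)))
  ft <- sweep(ft, 2, h, "*")
  out <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / m
  out[, seq_len(n), drop = FALSE]
}

#' Filtered back-projection of a single slice
#'
#' Filters the sinogram rows ([filter_sinogram()]), back-projects with
#' linear interpolation along the detector and scales by
#' `pi / (2 n_angles)`. Angles are in degrees, counter-clockwise, with 0
#' sending rays along +y; the grid is square with rotation about the
#' central pixel. Linear in the sinogram.
#'
#' @param sino numeric matrix `n_angles x detector_width`.
#' @param angles projection angles in degrees, one per sinogram row.
#' @param cfg a [recon_config()].
#' @return Reconstructed square slice `detector_width x detector_width`.
#' @export
fbp_slice <- function(sino, angles, cfg = recon_config()) {
  if (!is.matrix(sino)) stop("fbp_slice: 'sino' must be a matrix")
  if (nrow(sino) != length(angles))
    stop("fbp_slice: number of sinogram rows must equal length(angles)")
  n <- ncol(sino)
  fsino <- filter_sinogram(sino, cfg)
  rec <- cpp_backproject(fsino, angles * pi / 180, n) * pi / (2 * length(angles))
  if (cfg$circle_mask) {
    c0 <- (n - 1) / 2
    xy <- seq_len(n) - 1
    rec[outer((xy - c0)^2, (xy - c0)^2, "+") > c0^2] <- 0
  }
  rec
}

#' Reconstruct a volume from an attenuation projection stack
#'
#' Applies [fbp_slice()] independently to every detector row (z slice).
#'
#' @param stack a [projection_stack()] in the attenuation domain (a
#'   transmission stack is first passed through [to_sinograms()]).
#' @param cfg a [recon_config()].
#' @return A [volume()]; `provenance` records the filter and the stack id.
#' @export
reconstruct_volume <- function(stack, cfg = recon_config()) {
  if (!inherits(stack, "projection_stack"))
    stop("reconstruct_volume: 'stack' must be a projection_stack")
  if (stack$domain == "transmission") stack <- to_sinograms(stack)
  d <- dim(stack$images)
  if (d[3] < 1) stop("reconstruct_volume: stack is empty")
  vol <- array(0, c(d[2], d[2], d[1]))
  for (z in seq_len(d[1])) {
    sino <- t(stack$images[z, , ])        # n_angles x detector_width
    vol[, , z] <- fbp_slice(sino, stack$angles, cfg)
  }
  volume(vol, voxel_size = stack$pixel_size,
         provenance = sprintf("fbp(%s) of %s", cfg$filter_name,
                              if (nzchar(stack$id)) stack$id else "stack"))
}
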