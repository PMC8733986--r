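#' Acquisition specification for the simulated TXM scan
#'
#' Describes how noisy transmission projections are produced from ideal
#' attenuation line integrals: expected detector counts follow Beer–Lambert,
#' `I0(u, v) * exp(-A)`, with a spatially varying illumination profile
#' `I0`, Poisson photon statistics and optional zero-mean Gaussian detector
#' noise. The default illumination is a separable raised cosine falling to
#' `edge_level` (25%) of the central intensity at the detector edges, which
#' reproduces the condenser-subfield inhomogeneity of full-field microscopes:
#' the noise level of `-log` transmission increases towards the illumination
#' edges as 1/counts.
#'
#' @param n_angles number of projection angles (>= 1).
#' @param angle_range angular range in degrees; angles are equally spaced on
#'   the half-open interval `[0, angle_range)`.
#' @param mean_counts expected photon counts at the centre of the
#'   illumination profile (profile maximum).
#' @param edge_level illumination at the detector edge as a fraction of the
#'   centre (in (0, 1]).
#' @param detector_gaussian_sd standard deviation of additive zero-mean
#'   Gaussian detector noise, in counts.
#' @param seed integer seed for the noise draws.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_angles = 256, angle_range = 180,
                             mean_counts = 1000, edge_level = 0.25,
                             detector_gaussian_sd = 0, seed = 1) {
  if (!is.numeric(n_angles) || length(n_angles) != 1 || n_angles < 1)
    stop("acquisition_spec: 'n_angles' must be >= 1")
  if (!is.numeric(angle_range) || angle_range <= 0)
    stop("acquisition_spec: 'angle_range' must be > 0")
  if (!is.numeric(mean_counts) || mean_counts <= 0)
    stop("acquisition_spec: 'mean_counts' must be > 0")
  if (!is.numeric(edge_level) || edge_level <= 0 || edge_level > 1)
    stop("acquisition_spec: 'edge_level' must be in (0, 1]")
  if (!is.numeric(detector_gaussian_sd) || detector_gaussian_sd < 0)
    stop("acquisition_spec: 'detector_gaussian_sd' must be >= 0")
  structure(list(n_angles = as.integer(n_angles), angle_range = angle_range,
                 mean_counts = mean_counts, edge_level = edge_level,
                 detector_gaussian_sd = detector_gaussian_sd,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Projection angles of an acquisition
#' @param acq an [acquisition_spec()].
#' @return numeric vector of angles in degrees, equally spaced over
#'   `[0, angle_range)`.
#' @export
acquisition_angles <- function(acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  seq(0, acq$angle_range, length.out = acq$n_angles + 1L)[seq_len(acq$n_angles)]
}

#' Illumination profile on a detector grid
#'
#' Separable raised cosine, maximal (`mean_counts`) at the detector centre
#' and falling to `edge_level * mean_counts` at the edges.
#'
#' @param acq an [acquisition_spec()].
#' @param rows,cols detector dimensions in pixels.
#' @return matrix `rows x cols` of expected flat-field counts, all > 0.
#' @export
illumination_profile <- function(acq, rows, cols) {
  stopifnot(inherits(acq, "acquisition_spec"))
  w <- function(n) {
    if (n == 1) return(1)
    c0 <- (n - 1) / 2
    e <- acq$edge_level
    i <- seq_len(n) - 1
    e + (1 - e) * 0.5 * (1 + cos(pi * (i - c0) / c0))
  }
  acq$mean_counts * outer(w(rows), w(cols))
}

#' Parallel-beam forward projection of a volume
#'
#' Slice-wise Radon transform: the rotation axis is the volume z axis, and
#' each z slice is projected independently onto a 1-D detector row. Rays are
#' integrated by rotating the slice about its central pixel with bilinear
#' interpolation and summing along the beam axis, so the line integral of a
#' uniform object matches its chord length. Linear in the volume.
#'
#' @param vol a [volume()] of attenuation per voxel.
#' @param angles projection angles in degrees (nonempty).
#' @return A [projection_stack()] in the attenuation domain with
#'   `rows = nz`, `cols = nx` and one image per angle.
#' @export
forward_project <- function(vol, angles) {
  if (!inherits(vol, "txm_volume")) stop("forward_project: 'vol' must be a txm_volume")
  if (length(angles) == 0) stop("forward_project: 'angles' must be nonempty")
  d <- dim(vol$data)
  theta <- angles * pi / 180
  imgs <- array(0, c(d[3], d[2], length(angles)))
  for (z in seq_len(d[3])) {
    sino <- cpp_project_slice(vol$data[, , z], theta)   # n_angles x n
    imgs[z, , ] <- t(sino)
  }
  # line integrals are per-voxel attenuation times path length in voxels
  projection_stack(imgs, angles,
                   pixel_size = vol$voxel_size, domain = "attenuation",
                   id = vol$provenance)
}

#' Simulate noisy photon counting
#'
#' Converts ideal attenuation line integrals into noisy transmission images:
#' expected counts are `I0(u, v) * exp(-A)`, realised counts are Poisson
#' draws plus independent zero-mean Gaussian detector noise, and the output
#' transmission is `counts / I0` clipped to a small positive floor (1e-6)
#' so the subsequent log transform stays finite. Deterministic given
#' `acq$seed`.
#'
#' @param stack a [projection_stack()] in the attenuation domain.
#' @param acq an [acquisition_spec()].
#' @return A [projection_stack()] in the transmission domain.
#' @export
simulate_counts <- function(stack, acq) {
  if (!inherits(stack, "projection_stack") || stack$domain != "attenuation")
    stop("simulate_counts: 'stack' must be an attenuation projection_stack")
  if (!inherits(acq, "acquisition_spec"))
    stop("simulate_counts: 'acq' must be an acquisition_spec")
  d <- dim(stack$images)
  i0 <- illumination_profile(acq, d[1], d[2])
  if (any(i0 <= 0)) stop("simulate_counts: illumination must be > 0 everywhere")
  lambda <- as.vector(array(i0, d) * exp(-stack$images))
  set.seed(acq$seed)
  counts <- stats::rpois(length(lambda), lambda)
  if (acq$detector_gaussian_sd > 0)
    counts <- counts + stats::rnorm(length(counts), 0, acq$detector_gaussian_sd)
  trans <- pmax(array(counts, d) / array(i0, d), 1e-6)
  projection_stack(trans, stack$angles, pixel_size = stack$pixel_size,
                   domain = "transmission", id = stack$id)
}

#' Log transform transmission images to attenuation sinograms
#'
#' `-log(transmission)`: the exact inverse of the noise-free Beer–Lambert
#' map, applied before reconstruction.
#'
#' @param stack a [projection_stack()] in the transmission domain.
#' @return A [projection_stack()] in the attenuation domain.
#' @export
to_sinograms <- function(stack) {
  if (!inherits(stack, "projection_stack") || stack$domain != "transmission")
    stop("to_sinograms: 'stack' must be a transmission projection_stack")
  bad <- which(stack$images <= 0)
  if (length(bad))
    stop(sprintf("to_sinograms: nonpositive transmission at linear index %d", bad[1]))
  projection_stack(-log(stack$images), stack$angles,
                   pixel_size = stack$pixel_size, domain = "attenuation",
                   id = stack$id)
}
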