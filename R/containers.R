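#' Reconstructed or phantom volume
#'
#' Light-weight container for a 3-D grid of grey values (attenuation per
#' voxel for phantoms, reconstructed grey values otherwise). The in-plane
#' grid is required to be square, matching the reconstruction geometry.
#'
#' @param data numeric array `ny x nx x nz` (a matrix is promoted to a
#'   single-slice volume), all values finite, `ny == nx`.
#' @param voxel_size edge length of one voxel, in physical length units.
#' @param provenance free-text note on how the volume was produced (which
#'   projection half, which filter, ...).
#' @return An object of class `txm_volume` with elements `data`,
#'   `voxel_size` and `provenance`.
#' @export
volume <- function(data, voxel_size = 1, provenance = "") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume: 'data' must be a 3-D array (ny x nx x nz)")
  if (dim(data)[1] != dim(data)[2])
    stop("volume: in-plane grid must be square (ny == nx)")
  if (!all(is.finite(data)))
    stop("volume: all values must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("volume: 'voxel_size' must be a positive scalar")
  structure(list(data = data, voxel_size = voxel_size,
                 provenance = as.character(provenance)),
            class = "txm_volume")
}

#' @export
print.txm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<txm_volume> %d x %d x %d voxels, voxel size %g\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.txm_volume <- function(x) dim(x$data)

#' Stack of 2-D projection images with rotation angles
#'
#' Images are stored as an array `rows x cols x n_angles`; row index runs
#' along the rotation axis (one sinogram row per detector row), column index
#' along the detector. The `domain` tag distinguishes transmission images
#' (counts normalised by illumination, values in (0, 1] up to noise) from
#' attenuation line integrals (`-log` transmission).
#'
#' @param images numeric array `rows x cols x n_angles`.
#' @param angles rotation angles in degrees, one per image.
#' @param pixel_size detector pixel size in physical length units.
#' @param domain `"attenuation"` or `"transmission"`.
#' @param id free-text identifier carried through splitting/reconstruction.
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(images, angles, pixel_size = 1,
                             domain = c("attenuation", "transmission"),
                             id = "") {
  domain <- match.arg(domain)
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  if (!is.array(images) || length(dim(images)) != 3L)
    stop("projection_stack: 'images' must be a 3-D array (rows x cols x n_angles)")
  if (length(angles) != dim(images)[3])
    stop("projection_stack: length(angles) must equal the number of images")
  if (domain == "transmission" && any(images <= 0))
    stop("projection_stack: transmission values must be > 0")
  if (!all(is.finite(images)))
    stop("projection_stack: all values must be finite")
  structure(list(images = images, angles = as.numeric(angles),
                 pixel_size = pixel_size, domain = domain,
                 id = as.character(id)),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<projection_stack> %d projections of %d x %d px (%s domain)\n",
              d[3], d[1], d[2], x$domain))
  cat(sprintf("  angles %.2f..%.2f deg, pixel size %g\n",
              min(x$angles), max(x$angles), x$pixel_size))
  if (nzchar(x$id)) cat("  id:", x$id, "\n")
  invisible(x)
}

#' Number of projections in a stack
#' @param stack a [projection_stack()].
#' @return integer count.
#' @export
n_projections <- function(stack) {
  stopifnot(inherits(stack, "projection_stack"))
  dim(stack$images)[3]
}
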