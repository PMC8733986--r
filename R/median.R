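#' 3-D median baseline filter
#'
#' Replaces every voxel by the exact median of its neighbourhood — the
#' conventional post-reconstruction baseline the self-supervised filter is
#' benchmarked against. The neighbourhood of radius r is the
#' `(2r+1)^3` cube by default, with a Euclidean ball option; edges are
#' handled by mirror reflection. Order statistics are exact.
#'
#' @param vol a [volume()] strictly larger than the neighbourhood.
#' @param radius neighbourhood radius in voxels (>= 1, default 2).
#' @param shape `"cube"` (default) or `"ball"`.
#' @return A filtered [volume()].
#' @export
median3d <- function(vol, radius = 2, shape = c("cube", "ball")) {
  shape <- match.arg(shape)
  if (!inherits(vol, "txm_volume")) stop("median3d: 'vol' must be a txm_volume")
  if (!is.numeric(radius) || radius < 1) stop("median3d: 'radius' must be >= 1")
  radius <- as.integer(radius)
  if (any(dim(vol$data) < 2L * radius + 1L))
    stop("median3d: volume smaller than the filter neighbourhood")
  out <- cpp_median3d(vol$data, radius, shape == "ball")
  volume(array(out, dim(vol$data)), voxel_size = vol$voxel_size,
         provenance = sprintf("median3d(r=%d,%s) of %s", radius, shape,
                              vol$provenance))
}

#' 2-D median filtering of the projections
#'
#' Applies an exact 2-D median filter to every projection image before
#' reconstruction (projection-domain filtering, as opposed to [median3d()]
#' on the reconstructed stack).
#'
#' @param stack a [projection_stack()].
#' @param radius neighbourhood radius in pixels (>= 1, default 2).
#' @param shape `"cube"` (square neighbourhood) or `"ball"` (disc).
#' @return A filtered [projection_stack()].
#' @export
median2d_projections <- function(stack, radius = 2, shape = c("cube", "ball")) {
  shape <- match.arg(shape)
  if (!inherits(stack, "projection_stack"))
    stop("median2d_projections: 'stack' must be a projection_stack")
  if (!is.numeric(radius) || radius < 1)
    stop("median2d_projections: 'radius' must be >= 1")
  radius <- as.integer(radius)
  d <- dim(stack$images)
  if (any(d[1:2] < 2L * radius + 1L))
    stop("median2d_projections: projections smaller than the filter neighbourhood")
  out <- stack$images
  for (a in seq_len(d[3]))
    out[, , a] <- cpp_median2d(stack$images[, , a], radius, shape == "ball")
  projection_stack(out, stack$angles, pixel_size = stack$pixel_size,
                   domain = stack$domain,
                   id = sprintf("median2d(r=%d) of %s", radius, stack$id))
}
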