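#' Phantom specification
#'
#' Describes a synthetic 3-D test object. Three kinds are available:
#' \describe{
#'   \item{`lattice`}{an attenuating cylindrical slab pierced by a 3-D
#'     rectangular array of spherical holes with the given period — a
#'     stand-in for periodic porous microstructures (e.g. the optical
#'     nanostructure of a butterfly wing scale).}
#'   \item{`disk`}{a solid attenuating cylinder of radius `feature_radius`,
#'     used for analytic chord-length checks.}
#'   \item{`channels`}{an attenuating cylinder pierced by straight tubes
#'     2–3 voxels wide in randomised directions — a stand-in for
#'     canalicular networks in bone.}
#' }
#' The seed fixes the randomised details (lattice phase offset, channel
#' placement), so different seeds give distinct but statistically identical
#' phantom instances.
#'
#' @param kind `"lattice"`, `"disk"` or `"channels"`.
#' @param grid_size voxels per edge of the isotropic 3-D grid (>= 16).
#' @param period lattice period in voxels (lattice kind, >= 2).
#' @param wall_attenuation attenuation per voxel of the solid material (> 0).
#' @param feature_radius radius in voxels (disk kind: cylinder radius;
#'   channels kind: tube radius, default 1.25 giving 2–3 voxel wide tubes).
#' @param seed integer seed for the randomised geometry details.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("lattice", "disk", "channels"),
                         grid_size = 64, period = 8,
                         wall_attenuation = 0.02,
                         feature_radius = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(grid_size) || length(grid_size) != 1 || grid_size < 16)
    stop("phantom_spec: 'grid_size' must be a single number >= 16")
  if (!is.numeric(period) || length(period) != 1 || period < 2)
    stop("phantom_spec: 'period' must be a single number >= 2")
  if (!is.numeric(wall_attenuation) || length(wall_attenuation) != 1 ||
      wall_attenuation <= 0)
    stop("phantom_spec: 'wall_attenuation' must be > 0")
  if (is.null(feature_radius))
    feature_radius <- if (kind == "channels") 1.25 else grid_size / 4
  if (!is.numeric(feature_radius) || length(feature_radius) != 1 ||
      feature_radius < 0)
    stop("phantom_spec: 'feature_radius' must be >= 0")
  structure(list(kind = kind, grid_size = as.integer(grid_size),
                 period = period, wall_attenuation = wall_attenuation,
                 feature_radius = feature_radius, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a ground-truth phantom volume
#'
#' Deterministic given `spec$seed`. Values lie in
#' `[0, spec$wall_attenuation]`; the background is exactly 0. All solid
#' material is kept inside the circle inscribed in the in-plane grid so that
#' parallel-beam projections never truncate the object.
#'
#' @param spec a [phantom_spec()].
#' @return A [volume()] of attenuation per voxel.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("make_phantom: 'spec' must be a phantom_spec")
  n <- spec$grid_size
  c0 <- (n - 1) / 2
  mu <- spec$wall_attenuation
  xy <- seq_len(n) - 1
  r2 <- outer((xy - c0)^2, (xy - c0)^2, "+")  # [y, x] squared radius
  vol <- array(0, c(n, n, n))

  if (spec$kind == "disk") {
    disk <- r2 < spec$feature_radius^2
    vol[] <- rep(mu * disk, n)
  } else {
    slab_r <- 0.4 * n
    slab <- r2 < slab_r^2
    vol[] <- rep(mu * slab, n)
    if (spec$kind == "lattice") {
      p <- spec$period
      set.seed(spec$seed)
      phase <- sample.int(ceiling(p), 3, replace = TRUE) - 1
      hole_r <- 0.3 * p
      centres <- lapply(phase, function(ph) seq(ph, n - 1, by = p))
      # distance to the nearest hole centre, per axis, on the voxel grid
      dmin <- function(ph) {
        d <- abs(outer(xy, centres[[ph]], "-"))
        apply(d, 1, min)
      }
      dy <- dmin(1); dx <- dmin(2); dz <- dmin(3)
      d2 <- outer(outer(dy^2, dx^2, "+"), dz^2, "+")
      vol[d2 < hole_r^2] <- 0
    } else {  # channels
      set.seed(spec$seed)
      n_tubes <- max(3L, n %/% 16L)
      coords <- as.matrix(expand.grid(y = xy, x = xy, z = xy))
      for (k in seq_len(n_tubes)) {
        p0 <- runif(3, 0.25 * n, 0.75 * n)
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        rel <- sweep(coords, 2, p0)
        along <- rel %*% dir
        perp2 <- rowSums(rel^2) - along^2
        vol[perp2 < spec$feature_radius^2] <- 0
      }
    }
  }
  volume(vol, provenance = sprintf("phantom:%s seed %d", spec$kind, spec$seed))
}
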