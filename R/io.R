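#' Read and write projection stacks and volumes as 32-bit float TIFF
#'
#' Stacks and volumes are written as multi-page 32-bit TIFF plus a YAML
#' sidecar (`<basename>.yml`) holding the metadata (angles in degrees,
#' pixel/voxel size, domain tag, id/provenance) and the affine rescaling
#' (`data_min`, `data_max`) used to map the grey values into the TIFF's
#' storable range; reading restores the original values. The roundtrip is
#' exact to about 1e-9 of the dynamic range (32-bit quantisation).
#' Readers accept either a multi-page TIFF file or a directory of
#' single-page per-image TIFFs (sorted by name), which is normalised
#' internally; the sidecar is required and a missing one is an explicit
#' error naming the expected file.
#'
#' @param stack a [projection_stack()].
#' @param vol a [volume()].
#' @param path for writers: output TIFF path (sidecar written alongside);
#'   for readers: a multi-page TIFF or a directory of TIFFs.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name stack_io
NULL

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "metadata.yml")
  else paste0(sub("\\.tiff?$", "", path), ".yml")
}

write_pages <- function(arr3, path) {
  lo <- min(arr3); hi <- max(arr3)
  scaled <- if (hi > lo) (arr3 - lo) / (hi - lo) else arr3 * 0
  pages <- lapply(seq_len(dim(arr3)[3]), function(i) scaled[, , i])
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  c(data_min = lo, data_max = hi)
}

read_pages <- function(path, meta) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF files found in directory ", path)
    pages <- unlist(lapply(files, tiff::readTIFF, all = TRUE), recursive = FALSE)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
  }
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  meta$data_min + arr * (meta$data_max - meta$data_min)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("expected metadata sidecar not found: ", sc)
  yaml::read_yaml(sc)
}

#' @rdname stack_io
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "projection_stack"))
  rng <- write_pages(stack$images, path)
  yaml::write_yaml(list(type = "projection_stack",
                        angles = stack$angles,
                        pixel_size = stack$pixel_size,
                        domain = stack$domain, id = stack$id,
                        data_min = unname(rng["data_min"]),
                        data_max = unname(rng["data_max"])),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname stack_io
#' @export
read_stack <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "projection_stack"))
    stop("read_stack: sidecar does not describe a projection_stack")
  imgs <- read_pages(path, meta)
  projection_stack(imgs, meta$angles, pixel_size = meta$pixel_size,
                   domain = meta$domain, id = meta$id %||% "")
}

#' @rdname stack_io
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "txm_volume"))
  rng <- write_pages(vol$data, path)
  yaml::write_yaml(list(type = "volume",
                        voxel_size = vol$voxel_size,
                        provenance = vol$provenance,
                        data_min = unname(rng["data_min"]),
                        data_max = unname(rng["data_max"])),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname stack_io
#' @export
read_volume <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "volume"))
    stop("read_volume: sidecar does not describe a volume")
  arr <- read_pages(path, meta)
  volume(arr, voxel_size = meta$voxel_size, provenance = meta$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
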