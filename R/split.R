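#' Split a projection stack into two angle-interleaved halves
#'
#' The even half takes projections at 0-based indices 0, 2, 4, ... and the
#' odd half takes 1, 3, 5, ...; each image keeps its rotation angle. The two
#' halves partition the parent stack: no projection appears in both, their
#' union is the parent, and their sizes differ by at most one (an odd count
#' puts the extra projection in the even half). The photon noise in the two
#' halves is independent, which is what makes one half a valid regression
#' target for the other.
#'
#' @param stack a [projection_stack()] with at least 2 projections.
#' @return An object of class `split_pair` with elements `even`, `odd`
#'   (both [projection_stack()]s) and `parent_id`.
#' @export
split_projections <- function(stack) {
  if (!inherits(stack, "projection_stack"))
    stop("split_projections: 'stack' must be a projection_stack")
  n <- n_projections(stack)
  if (n < 2) stop("split_projections: need at least 2 projections")
  take <- function(idx, tag) {
    projection_stack(stack$images[, , idx, drop = FALSE], stack$angles[idx],
                     pixel_size = stack$pixel_size, domain = stack$domain,
                     id = paste0(tag, " half of ",
                                 if (nzchar(stack$id)) stack$id else "stack"))
  }
  structure(list(even = take(seq(1, n, by = 2), "even"),
                 odd = take(seq(2, n, by = 2), "odd"),
                 parent_id = stack$id),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("<split_pair> even: %d projections, odd: %d projections\n",
              n_projections(x$even), n_projections(x$odd)))
  invisible(x)
}

# mirror reflection of a 1-based z index without edge repeat:
# 0 -> 2, -1 -> 3, nz+1 -> nz-1
reflect_index <- function(z, nz) {
  if (nz == 1) return(rep(1L, length(z)))
  period <- 2L * (nz - 1L)
  z <- (z - 1L) %% period
  z <- ifelse(z >= nz, period - z, z)
  as.integer(z + 1L)
}

#' Build the paired multi-channel slice dataset for training
#'
#' For every z index in the training and validation ranges the input is the
#' `(2k+1)`-channel image `volA[z-k ... z+k]` (mirror-reflected at the
#' volume boundaries) and the target is the single slice `volB[z]`. The two
#' roles must be disjoint and separated by a guard gap so that validation
#' slices are not directly neighbouring the training slices.
#'
#' @param volA,volB two [volume()]s of identical shape (the two
#'   half-reconstructions).
#' @param k channel half-width; the input has `2k+1` channels (default 2,
#'   i.e. the slice plus its closest adjacent slices).
#' @param train_range,val_range integer vectors of 1-based z indices.
#' @param guard minimum index distance required between the two ranges
#'   (default 10).
#' @return An object of class `slice_pair_dataset` with elements `inputs`
#'   (list of `ny x nx x (2k+1)` arrays), `targets` (list of matrices),
#'   `z`, `role` (`"train"`/`"val"`), `k`, plus the source volumes and
#'   ranges (needed by [swap_roles()]).
#' @export
build_slice_pairs <- function(volA, volB, k = 2, train_range, val_range,
                              guard = 10) {
  if (!inherits(volA, "txm_volume") || !inherits(volB, "txm_volume"))
    stop("build_slice_pairs: volumes must be txm_volume objects")
  if (!identical(dim(volA$data), dim(volB$data)))
    stop("build_slice_pairs: volumes must have identical shape")
  if (!is.numeric(k) || length(k) != 1 || k < 0)
    stop("build_slice_pairs: 'k' must be >= 0")
  k <- as.integer(k)
  nz <- dim(volA$data)[3]
  train_range <- as.integer(train_range); val_range <- as.integer(val_range)
  if (any(c(train_range, val_range) < 1) || any(c(train_range, val_range) > nz))
    stop("build_slice_pairs: ranges must lie within 1..nz")
  if (length(intersect(train_range, val_range)))
    stop("build_slice_pairs: train and validation ranges overlap")
  gap <- min(abs(outer(train_range, val_range, "-")))
  if (gap < guard)
    stop(sprintf("build_slice_pairs: ranges are %d slices apart; guard gap of %d required",
                 gap, guard))
  zs <- c(train_range, val_range)
  role <- rep(c("train", "val"), c(length(train_range), length(val_range)))
  d <- dim(volA$data)
  inputs <- lapply(zs, function(z) {
    ch <- reflect_index(seq(z - k, z + k), nz)
    volA$data[, , ch, drop = FALSE]
  })
  targets <- lapply(zs, function(z) volB$data[, , z])
  structure(list(inputs = inputs, targets = targets, z = zs, role = role,
                 k = k, volA = volA, volB = volB,
                 train_range = train_range, val_range = val_range,
                 guard = guard),
            class = "slice_pair_dataset")
}

#' @export
print.slice_pair_dataset <- function(x, ...) {
  cat(sprintf("<slice_pair_dataset> %d train + %d validation pairs, %d channels\n",
              sum(x$role == "train"), sum(x$role == "val"), 2 * x$k + 1))
  invisible(x)
}

#' Exchange the input and target volumes of a slice-pair dataset
#'
#' Returns the dataset rebuilt with the roles of the two half-reconstructions
#' exchanged (B becomes the regressor, A the regressand). Applying it twice
#' restores the original dataset. Useful for symmetric training, which is
#' off by default.
#'
#' @param ds a [build_slice_pairs()] dataset.
#' @return A `slice_pair_dataset`.
#' @export
swap_roles <- function(ds) {
  if (!inherits(ds, "slice_pair_dataset"))
    stop("swap_roles: 'ds' must be a slice_pair_dataset")
  build_slice_pairs(ds$volB, ds$volA, k = ds$k,
                    train_range = ds$train_range, val_range = ds$val_range,
                    guard = ds$guard)
}
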