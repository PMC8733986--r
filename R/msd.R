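#' Mixed-scale dense network configuration
#'
#' The network has `depth` hidden feature layers of width one. Hidden layer
#' i computes a single feature map as a ReLU-activated sum of 3x3 dilated
#' convolutions (zero padding, dilation cycling through `dilation_cycle`)
#' over all previous feature maps, including the input channels; the output
#' layer is a learned 1x1 linear combination of every input and hidden map
#' plus a bias. Mixing dilations across densely connected width-one layers
#' gives a large receptive field with very few parameters, which is what
#' makes the architecture trainable on a few hundred slices.
#'
#' @param depth number of hidden feature layers (>= 1, default 30).
#' @param dilation_cycle integer dilations cycled over the hidden layers
#'   (default `1:10`).
#' @param in_channels number of input channels, `2k+1` for channel
#'   half-width k (odd, >= 1, default 5).
#' @param seed integer seed for the weight initialisation.
#' @return An object of class `msd_config`.
#' @export
msd_config <- function(depth = 30, dilation_cycle = 1:10, in_channels = 5,
                       seed = 1) {
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1)
    stop("msd_config: 'depth' must be >= 1")
  if (!is.numeric(dilation_cycle) || any(dilation_cycle < 1))
    stop("msd_config: all dilations must be >= 1")
  if (!is.numeric(in_channels) || length(in_channels) != 1 ||
      in_channels < 1 || in_channels %% 2 != 1)
    stop("msd_config: 'in_channels' must be odd and >= 1")
  depth <- as.integer(depth)
  structure(list(depth = depth,
                 dilations = as.integer(dilation_cycle[((seq_len(depth) - 1) %%
                                        length(dilation_cycle)) + 1]),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "msd_config")
}

#' Number of trainable parameters of an MSD network
#'
#' Hidden layer i has `9 * (in_channels + i - 1)` convolution weights plus
#' one bias; the output layer has `in_channels + depth` weights plus one
#' bias.
#'
#' @param cfg an [msd_config()].
#' @return integer parameter count.
#' @export
msd_n_params <- function(cfg) {
  stopifnot(inherits(cfg, "msd_config"))
  c0 <- cfg$in_channels
  hidden <- sum(9L * (c0 + seq_len(cfg$depth) - 1L) + 1L)
  hidden + (c0 + cfg$depth) + 1L
}

#' Initialise MSD network weights
#'
#' He-style normal initialisation for the hidden convolutions (standard
#' deviation `sqrt(2 / fan_in)` with `fan_in = 9 * n_incoming_maps`), zero
#' biases, and a zero output layer (the network starts as the zero map and
#' learns residual structure on standardised data). Deterministic given
#' `cfg$seed`.
#'
#' @param cfg an [msd_config()].
#' @return numeric weight vector of length [msd_n_params()].
#' @export
msd_init_weights <- function(cfg) {
  stopifnot(inherits(cfg, "msd_config"))
  set.seed(cfg$seed)
  c0 <- cfg$in_channels
  w <- numeric(msd_n_params(cfg))
  p <- 0L
  for (li in seq_len(cfg$depth)) {
    nin <- c0 + li - 1L
    w[p + seq_len(9L * nin)] <- stats::rnorm(9L * nin, 0, sqrt(2 / (9 * nin)))
    p <- p + 9L * nin + 1L  # bias stays 0
  }
  w  # output layer stays 0
}

#' Run an MSD network forward on one multi-channel image
#'
#' @param weights weight vector (layout of [msd_init_weights()]).
#' @param input numeric array `ny x nx x in_channels` (a matrix is promoted
#'   to one channel).
#' @param cfg an [msd_config()].
#' @return numeric matrix `ny x nx`; spatial shape always equals the input
#'   (zero-padded convolutions).
#' @export
msd_forward <- function(weights, input, cfg) {
  stopifnot(inherits(cfg, "msd_config"))
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  if (dim(input)[3] != cfg$in_channels)
    stop("msd_forward: input channel count does not match 'cfg$in_channels'")
  if (length(weights) != msd_n_params(cfg))
    stop("msd_forward: weight vector has wrong length")
  cpp_msd_forward(weights, input, cfg$dilations)
}

#' Training configuration
#'
#' @param max_epochs maximum number of passes over the training pairs
#'   (>= 1, default 100).
#' @param patience epochs without a new validation minimum before training
#'   stops (>= 1, default 10).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size slices per gradient step (default 2).
#' @param seed integer seed for the epoch shuffling.
#' @return An object of class `train_config`. The loss is always the
#'   mean-squared error between network output and target slice.
#' @export
train_config <- function(max_epochs = 100, patience = 10,
                         learning_rate = 1e-3, batch_size = 2, seed = 1) {
  if (!is.numeric(max_epochs) || max_epochs < 1)
    stop("train_config: 'max_epochs' must be >= 1")
  if (!is.numeric(patience) || patience < 1)
    stop("train_config: 'patience' must be >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("train_config: 'learning_rate' must be > 0")
  if (!is.numeric(batch_size) || batch_size < 1)
    stop("train_config: 'batch_size' must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Early-stopping decision on a validation curve
#'
#' Pure function implementing the stopping rule used during training: the
#' retained epoch is the argmin of the validation curve seen so far, and
#' training stops once `patience` consecutive epochs have passed without a
#' new minimum (or at the end of the curve).
#'
#' @param val_curve numeric vector of per-epoch validation MSE values.
#' @param patience epochs without improvement tolerated before stopping.
#' @return list with `best_epoch` (1-based argmin of the curve up to the
#'   stopping point), `stop_epoch`, and `stop_reason`
#'   (`"patience"` or `"max_epochs"`).
#' @export
select_best_epoch <- function(val_curve, patience) {
  stopifnot(length(val_curve) >= 1, patience >= 1)
  best <- 1L
  for (e in seq_along(val_curve)) {
    if (val_curve[e] < val_curve[best]) best <- e
    if (e - best >= patience)
      return(list(best_epoch = best, stop_epoch = e, stop_reason = "patience"))
  }
  list(best_epoch = best, stop_epoch = length(val_curve),
       stop_reason = "max_epochs")
}

#' Fit a self-supervised MSD denoiser
#'
#' Trains a mixed-scale dense network to regress the input
#' half-reconstruction onto the other half (Noise2Inverse): because the
#' photon noise of the two halves is independent, only the signal shared by
#' both is regressed and the minimiser of the expected MSE is the clean
#' signal. Inputs and targets are standardised by the training-set mean and
#' standard deviation (stored in the model, so inference is
#' self-contained); optimisation is Adam on the mean-squared error;
#' training stops early at the minimum of the validation MSE
#' ([select_best_epoch()]) and the weights of that epoch are retained.
#' Single-threaded and deterministic given the seeds.
#'
#' @param ds a [build_slice_pairs()] dataset with nonempty train and
#'   validation roles.
#' @param net an [msd_config()]; its `in_channels` must equal `2 ds$k + 1`.
#' @param training a [train_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `msd_denoiser` with elements `config`,
#'   `training`, `weights` (best-epoch weights), `input_stats`,
#'   `target_stats` (named `mean`/`sd` vectors), `best_epoch`, `log`
#'   (data frame of per-epoch train/validation MSE) and `stop_reason`.
#' @seealso [predict.msd_denoiser()], [denoise_new_scan()]
#' @export
msd_denoiser <- function(ds, net = msd_config(in_channels = 2 * ds$k + 1),
                         training = train_config(), verbose = FALSE) {
  if (!inherits(ds, "slice_pair_dataset"))
    stop("msd_denoiser: 'ds' must be a slice_pair_dataset")
  stopifnot(inherits(net, "msd_config"), inherits(training, "train_config"))
  if (net$in_channels != 2L * ds$k + 1L)
    stop("msd_denoiser: 'net$in_channels' must equal 2k+1 of the dataset")
  tr <- which(ds$role == "train"); va <- which(ds$role == "val")
  if (!length(tr) || !length(va))
    stop("msd_denoiser: dataset needs nonempty train and validation roles")

  in_mean <- mean(vapply(ds$inputs[tr], mean, 0))
  in_sd <- stats::sd(unlist(lapply(ds$inputs[tr], as.vector)))
  tg_mean <- mean(vapply(ds$targets[tr], mean, 0))
  tg_sd <- stats::sd(unlist(lapply(ds$targets[tr], as.vector)))
  if (!is.finite(in_sd) || in_sd <= 0 || !is.finite(tg_sd) || tg_sd <= 0)
    stop("msd_denoiser: degenerate (constant) training data")
  xin <- lapply(ds$inputs, function(a) (a - in_mean) / in_sd)
  ytg <- lapply(ds$targets, function(m) (m - tg_mean) / tg_sd)

  w <- msd_init_weights(net)
  mt <- vt <- numeric(length(w))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  lr <- training$learning_rate

  set.seed(training$seed)
  train_mse <- val_mse <- numeric(0)
  best_w <- w
  for (epoch in seq_len(training$max_epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / training$batch_size))
    ep_loss <- 0
    for (b in batches) {
      g <- numeric(length(w)); loss_b <- 0
      for (i in b) {
        res <- cpp_msd_grad(w, xin[[i]], ytg[[i]], net$dilations)
        g <- g + res$grad; loss_b <- loss_b + res$loss
      }
      g <- g / length(b); loss_b <- loss_b / length(b)
      if (!is.finite(loss_b))
        stop(sprintf("msd_denoiser: training diverged (non-finite loss) at epoch %d", epoch))
      t_step <- t_step + 1
      mt <- b1 * mt + (1 - b1) * g
      vt <- b2 * vt + (1 - b2) * g^2
      w <- w - lr * (mt / (1 - b1^t_step)) / (sqrt(vt / (1 - b2^t_step)) + eps)
      ep_loss <- ep_loss + loss_b * length(b)
    }
    train_mse[epoch] <- ep_loss / length(tr)
    val_mse[epoch] <- mean(vapply(va, function(i) {
      mean((cpp_msd_forward(w, xin[[i]], net$dilations) - ytg[[i]])^2)
    }, 0))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      train_mse[epoch], val_mse[epoch]))
    if (epoch == which.min(val_mse)) best_w <- w
    dec <- select_best_epoch(val_mse, training$patience)
    if (dec$stop_reason == "patience") break
  }
  dec <- select_best_epoch(val_mse, training$patience)

  structure(list(config = net, training = training, weights = best_w,
                 input_stats = c(mean = in_mean, sd = in_sd),
                 target_stats = c(mean = tg_mean, sd = tg_sd),
                 best_epoch = dec$best_epoch,
                 log = data.frame(epoch = seq_along(val_mse),
                                  train_mse = train_mse, val_mse = val_mse),
                 stop_reason = dec$stop_reason,
                 optimizer = sprintf("adam(lr=%g, batch=%d)", lr,
                                     training$batch_size)),
            class = "msd_denoiser")
}

#' @export
print.msd_denoiser <- function(x, ...) {
  cat(sprintf("<msd_denoiser> depth %d, %d input channels, %d parameters\n",
              x$config$depth, x$config$in_channels, msd_n_params(x$config)))
  cat(sprintf("  trained %d epochs (%s), best epoch %d, validation MSE %.5g\n",
              nrow(x$log), x$stop_reason, x$best_epoch,
              x$log$val_mse[x$best_epoch]))
  invisible(x)
}

#' @export
summary.msd_denoiser <- function(object, ...) {
  cat("Self-supervised MSD denoiser\n")
  print(object)
  cat(sprintf("  optimizer: %s\n", object$optimizer))
  cat(sprintf("  input stats: mean %.4g, sd %.4g; target stats: mean %.4g, sd %.4g\n",
              object$input_stats["mean"], object$input_stats["sd"],
              object$target_stats["mean"], object$target_stats["sd"]))
  cat(sprintf("  dilations: %s\n", paste(object$config$dilations, collapse = " ")))
  invisible(object)
}

#' @export
coef.msd_denoiser <- function(object, ...) object$weights

#' Plot training and validation MSE curves
#' @param x an [msd_denoiser()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.msd_denoiser <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_mse, x$log$val_mse),
                    type = "l", lty = 1, col = c("grey40", "red"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "red"), bty = "n")
  invisible(x)
}

#' Denoise a volume with a trained model
#'
#' For each z slice the `(2k+1)`-channel input is assembled with mirror
#' reflection at the volume boundaries, standardised with the stored input
#' statistics, run through the network, and de-standardised with the stored
#' target statistics. The output has the shape of the input volume.
#'
#' @param object an [msd_denoiser()] fit.
#' @param newdata a [volume()] of the same noise level the model was
#'   trained on (i.e. a half-reconstruction).
#' @param ... unused.
#' @return A denoised [volume()].
#' @export
predict.msd_denoiser <- function(object, newdata, ...) {
  if (!inherits(newdata, "txm_volume"))
    stop("predict.msd_denoiser: 'newdata' must be a txm_volume")
  if (is.null(object$input_stats) || is.null(object$target_stats))
    stop("predict.msd_denoiser: model is missing normalisation statistics")
  k <- (object$config$in_channels - 1L) %/% 2L
  d <- dim(newdata$data); nz <- d[3]
  out <- array(0, d)
  im <- object$input_stats["mean"]; isd <- object$input_stats["sd"]
  tm <- object$target_stats["mean"]; tsd <- object$target_stats["sd"]
  for (z in seq_len(nz)) {
    ch <- reflect_index(seq(z - k, z + k), nz)
    xin <- (newdata$data[, , ch, drop = FALSE] - im) / isd
    out[, , z] <- cpp_msd_forward(object$weights, xin,
                                  object$config$dilations) * tsd + tm
  }
  volume(out, voxel_size = newdata$voxel_size,
         provenance = paste0("msd-denoised ", newdata$provenance))
}

#' Denoise a new scan with an already-trained model
#'
#' A trained model expects the noise level of a half-reconstruction, so a
#' new full scan is first split into two angle-interleaved halves and only
#' the even half is reconstructed and denoised (the odd half is not
#' needed). This is what makes model reuse halve the acquisition time for
#' a series of structurally similar samples.
#'
#' @param model an [msd_denoiser()] fit.
#' @param stack a [projection_stack()] (transmission stacks are log
#'   transformed first), at least 2 projections.
#' @param rcfg a [recon_config()].
#' @return A denoised [volume()]; provenance records that the even half of
#'   the scan was used.
#' @export
denoise_new_scan <- function(model, stack, rcfg = recon_config()) {
  if (!inherits(model, "msd_denoiser"))
    stop("denoise_new_scan: 'model' must be an msd_denoiser")
  pair <- split_projections(stack)
  half <- reconstruct_volume(pair$even, rcfg)
  predict(model, half)
}

#' Save / load a trained denoiser
#'
#' The model (network config, weights, normalisation statistics, training
#' log) is serialised to a single RDS container file.
#'
#' @param model an [msd_denoiser()] fit.
#' @param path file path.
#' @return `load_denoiser` returns the [msd_denoiser()] object.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "msd_denoiser"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "msd_denoiser"))
    stop("load_denoiser: file does not contain an msd_denoiser")
  model
}
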