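#' Fit a mixed-scale dense segmentation network
#'
#' Trains an MS-D network for slice-wise binary bone segmentation. The model
#' is a stack of densely connected 3x3 dilated convolutions (one feature map
#' per layer, dilation cycling with the layer index, reflective boundaries)
#' feeding a two-class softmax; it is optimized with batch-size-1 Adam on a
#' per-pixel cross-entropy loss, one axial slice per step, in a freshly
#' shuffled order every epoch. Inputs are z-scored with statistics pooled
#' over the training volumes; the fitted statistics are stored in the object
#' and reapplied by `predict()`, so held-out volumes never contribute to
#' normalization.
#'
#' @param x Training images: a list of labeled volumes (elements with
#'   `$image` and `$bone_mask`, e.g. from [generate_dataset()]), a 3D array
#'   of axial slices, or a list of matrices.
#' @param y Binary bone masks matching `x`; omit when `x` is a list of
#'   labeled volumes.
#' @param depth Number of hidden convolutional layers.
#' @param dilation_cycle Period of the cyclic dilation schedule.
#' @param cutoff Default binarization threshold used by `predict(type =
#'   "mask")`.
#' @param epochs Passes over the training slices.
#' @param lr,beta1,beta2,eps Adam step size, moment decay rates and
#'   stabilizer (defaults 1e-3, 0.9, 0.999, 1e-8).
#' @param max_steps Optional cap on the total number of batch-size-1 steps.
#' @param seed Integer seed for initialization and slice shuffling; a fixed
#'   seed makes the fit fully deterministic on a given platform.
#' @param normalize If `FALSE`, slices are used as-is (assumed already
#'   normalized) and `predict()` applies no transform.
#' @return An object of class `"msd_fit"` with components `config`, `params`
#'   (flat parameter vector), `stats` (normalization), `loss` (per-epoch mean
#'   cross-entropy), `step_loss`, `n_slices`, `seed` and `call`.
#' @seealso [predict.msd_fit()], [run_cross_validation()],
#'   [sweep_hyperparameters()]
#' @examples
#' set.seed(1)
#' x <- array(rnorm(16 * 16 * 6), dim = c(16, 16, 6))
#' y <- array(0L, dim = dim(x)); y[5:12, 5:12, ] <- 1L
#' x[, , ] <- x[, , ] + 2 * y  # bone is brighter
#' fit <- msd_fit(x, y, depth = 3, epochs = 4, seed = 1)
#' fit
#' mask <- predict(fit, x[, , 1], type = "mask", cutoff = 0.5)
#' @export
msd_fit <- function(x, y = NULL, depth = 20L, dilation_cycle = 10L,
                    cutoff = 0.7, epochs = 10L, lr = 1e-3, beta1 = 0.9,
                    beta2 = 0.999, eps = 1e-8, max_steps = NULL, seed = 1L,
                    normalize = TRUE) {
  cl <- match.call()
  config <- msd_config(depth = depth, dilation_cycle = dilation_cycle,
                       cutoff = cutoff)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("'epochs' must be >= 1")
  data <- gather_slices(x, y)
  if (dim(data$slices)[3L] < 1L) stop("no training slices")

  stats <- NULL
  slices <- data$slices
  if (normalize) {
    stats <- compute_normalization(slices)
    slices <- apply_normalization(slices, stats)
  }
  params <- init_parameters(config, seed)
  run <- train_engine(slices, data$masks, params, config, epochs = epochs,
                      seed = seed, lr = lr, beta1 = beta1, beta2 = beta2,
                      eps = eps, max_steps = max_steps)
  structure(
    list(config = config, params = run$params, stats = stats,
         loss = run$epoch_losses, step_loss = run$step_losses,
         n_slices = dim(data$slices)[3L], seed = seed, call = cl),
    class = "msd_fit")
}

# Normalize the accepted training-data shapes into (slices, masks) cubes.
gather_slices <- function(x, y = NULL) {
  if (is.list(x) && is.null(y)) {
    imgs <- lapply(x, function(v) {
      if (is.null(v$image) || is.null(v$bone_mask))
        stop("labeled volumes need 'image' and 'bone_mask'")
      as_volume3d(v$image)
    })
    msks <- lapply(x, function(v) as_volume3d(v$bone_mask))
  } else if (is.list(x)) {
    imgs <- lapply(x, as_volume3d)
    msks <- lapply(y, as_volume3d)
  } else {
    imgs <- list(as_volume3d(x))
    msks <- list(as_volume3d(y))
  }
  if (length(msks) != length(imgs) ||
      !all(mapply(function(a, b) identical(dim(a), dim(b)), imgs, msks)))
    stop("images and masks must have identical shapes")
  dims <- unique(t(vapply(imgs, function(v) dim(v)[1:2], integer(2))))
  if (nrow(dims) != 1L) stop("all slices must share one in-plane size")
  n_slices <- sum(vapply(imgs, function(v) dim(v)[3L], integer(1)))
  slices <- array(unlist(imgs), dim = c(dims[1L, ], n_slices))
  masks <- array(as.numeric(unlist(msks)), dim = dim(slices))
  if (!all(masks %in% c(0, 1))) stop("masks must be binary (0/1)")
  list(slices = slices, masks = masks)
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("Mixed-scale dense segmentation network\n")
  cat(sprintf("  %d layers, dilation cycle %d, cutoff %.2f; %d parameters\n",
              x$config$depth, x$config$dilation_cycle, x$config$cutoff,
              count_parameters(x$config)))
  cat(sprintf("  trained on %d slices, %d epochs (%d steps)\n",
              x$n_slices, length(x$loss), length(x$step_loss)))
  cat(sprintf("  cross-entropy: first epoch %.4f, last epoch %.4f\n",
              x$loss[1L], x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
summary.msd_fit <- function(object, ...) {
  str <- structure_parameters(object$params, object$config)
  out <- list(config = object$config,
              n_parameters = count_parameters(object$config),
              n_slices = object$n_slices,
              loss = object$loss,
              kernel_sd = if (object$config$depth > 0)
                sd(unlist(str$kernels)) else NA_real_,
              out_weight_range = range(str$out_weights),
              stats = object$stats,
              seed = object$seed)
  class(out) <- "summary.msd_fit"
  out
}

#' @export
print.summary.msd_fit <- function(x, ...) {
  print(x$config)
  cat(sprintf("trained on %d slices (seed %d)\n", x$n_slices, x$seed))
  if (!is.null(x$stats)) print(x$stats)
  cat("per-epoch mean cross-entropy:\n")
  print(round(x$loss, 5))
  if (!is.na(x$kernel_sd))
    cat(sprintf("hidden kernel sd: %.4f; output weight range: [%.4f, %.4f]\n",
                x$kernel_sd, x$out_weight_range[1L], x$out_weight_range[2L]))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, structured = FALSE, ...) {
  if (structured) structure_parameters(object$params, object$config)
  else object$params
}

#' Segment new volumes with a fitted MS-D network
#'
#' Applies the training-set normalization stored in the fit, runs the network
#' on every axial slice, and returns either bone probabilities or the
#' binarized mask.
#'
#' @param object An `"msd_fit"`.
#' @param newdata A 3D array, a single slice matrix, or a labeled volume
#'   (its `$image` is used).
#' @param type `"prob"` for bone probabilities, `"mask"` for 0/1 labels.
#' @param cutoff Binarization threshold; defaults to the fitted
#'   configuration's cutoff.
#' @param ... Unused.
#' @return 3D array (or matrix, matching the input rank) of probabilities or
#'   integer labels.
#' @export
predict.msd_fit <- function(object, newdata, type = c("prob", "mask"),
                            cutoff = NULL, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.null(newdata$image)) newdata <- newdata$image
  was_matrix <- is.matrix(newdata)
  vol <- as_volume3d(newdata)
  if (!is.null(object$stats))
    vol <- apply_normalization(vol, object$stats)
  prob <- forward_volume(vol, object$params, object$config)
  out <- if (type == "prob") prob
  else binarize(prob, cutoff %||% object$config$cutoff)
  if (was_matrix) out <- out[, , 1L]
  out
}

#' Plot the training loss of an MS-D fit
#'
#' @param x An `"msd_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.msd_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean cross-entropy",
                 main = "MS-D training loss", ...)
  invisible(x)
}
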