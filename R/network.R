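#' Dilation factor of a hidden layer
#'
#' The dilation schedule starts at 1 in the first layer, grows by 1 per
#' layer, and resets to 1 after `cycle` layers, so layer `i` uses
#' `((i - 1) %% cycle) + 1`.
#'
#' @param i 1-based layer index (vectorized).
#' @param cycle Schedule period (default 10).
#' @return Integer dilation(s) in `1:cycle`.
#' @examples
#' dilation_for_layer(1:12)  # 1 2 ... 10 1 2
#' @export
dilation_for_layer <- function(i, cycle = 10L) {
  i <- as.integer(i)
  cycle <- as.integer(cycle)
  if (any(is.na(i)) || any(i < 1L)) stop("layer index must be >= 1")
  if (is.na(cycle) || cycle < 1L) stop("'cycle' must be >= 1")
  ((i - 1L) %% cycle) + 1L
}

#' Dilated 3x3 convolution with reflective boundaries
#'
#' Convolves a 2D map with a 3x3 kernel whose taps are spaced `dilation`
#' pixels apart. Out-of-range indices are mirrored about the border pixel
#' without duplicating it (index -k maps to +k), folding repeatedly, so the
#' output always has the input's shape.
#'
#' @param map Numeric matrix.
#' @param kernel 3x3 numeric matrix; row index is the row offset (-1, 0, +1),
#'   column index the column offset.
#' @param dilation Integer tap spacing >= 1.
#' @return Numeric matrix of the same shape as `map`.
#' @export
dilated_conv <- function(map, kernel, dilation = 1L) {
  map <- as.matrix(map)
  if (length(map) == 0L) stop("'map' must be nonempty")
  kernel <- as.matrix(kernel)
  if (!all(dim(kernel) == c(3L, 3L))) stop("'kernel' must be 3x3")
  dilation <- as.integer(dilation)
  if (is.na(dilation) || dilation < 1L) stop("'dilation' must be >= 1")
  storage.mode(map) <- "double"
  storage.mode(kernel) <- "double"
  cpp_dilated_conv(map, kernel, dilation)
}

#' Forward pass of one hidden MS-D layer
#'
#' Computes `z_i = ReLU(sum_j D(z_j, h_ij, s_i) + b_i)` from the feature
#' stack accumulated so far: each previously computed map (input included) is
#' convolved with its own 3x3 kernel at the layer's dilation and the results
#' are summed pixel-wise before bias and rectification.
#'
#' @param stack List of numeric matrices `z_0, ..., z_{i-1}`, all the same
#'   shape.
#' @param kernels List of 3x3 kernels, one per stack entry.
#' @param bias Scalar bias.
#' @param dilation Integer dilation of this layer.
#' @return The new feature map, same shape as the inputs.
#' @export
layer_forward <- function(stack, kernels, bias, dilation) {
  if (length(kernels) != length(stack))
    stop(sprintf("layer expects %d kernels for a stack of %d maps",
                 length(stack), length(kernels)))
  acc <- 0
  for (j in seq_along(stack))
    acc <- acc + dilated_conv(stack[[j]], kernels[[j]], dilation)
  pmax(acc + bias, 0)
}

#' Softmax output of an MS-D network
#'
#' Applies the 1x1 output convolution to a full feature stack: per pixel,
#' class logits are `sum_i w_ci z_i + b_c` and the two-class softmax turns
#' them into probabilities.
#'
#' @param stack List of `depth + 1` numeric matrices (input map plus every
#'   layer output).
#' @param out_weights 2 x (depth + 1) matrix; row 1 background, row 2 bone.
#' @param out_biases Length-2 numeric vector.
#' @return A probability array of dimension `c(nrow, ncol, 2)` with
#'   `[ , , 1]` the background and `[ , , 2]` the bone probability; class
#'   `"prob_map"`.
#' @export
output_probabilities <- function(stack, out_weights, out_biases) {
  out_weights <- as.matrix(out_weights)
  if (ncol(out_weights) != length(stack) || nrow(out_weights) != 2L)
    stop(sprintf("output weights must be 2 x %d", length(stack)))
  if (length(out_biases) != 2L) stop("'out_biases' must have length 2")
  dm <- dim(stack[[1L]])
  l0 <- matrix(out_biases[1L], dm[1L], dm[2L])
  l1 <- matrix(out_biases[2L], dm[1L], dm[2L])
  for (i in seq_along(stack)) {
    l0 <- l0 + out_weights[1L, i] * stack[[i]]
    l1 <- l1 + out_weights[2L, i] * stack[[i]]
  }
  m <- pmax(l0, l1)
  e0 <- exp(l0 - m)
  e1 <- exp(l1 - m)
  prob <- array(c(e0 / (e0 + e1), e1 / (e0 + e1)), dim = c(dm, 2L))
  class(prob) <- "prob_map"
  prob
}

#' Run an MS-D network on one axial slice
#'
#' Builds the full feature stack (input map, then each hidden layer at its
#' scheduled dilation) and applies the softmax output layer. Deterministic
#' for fixed parameters.
#'
#' @param slice Numeric matrix (a normalized axial slice).
#' @param params Flat numeric parameter vector (see
#'   [structure_parameters()]).
#' @param config An [msd_config()].
#' @param keep_stack If `TRUE`, also return the feature stack.
#' @return A `"prob_map"` array (`[ , , 2]` = bone probability); with
#'   `keep_stack = TRUE`, a list with elements `prob` and `stack`.
#' @export
forward_slice <- function(slice, params, config, keep_stack = FALSE) {
  stopifnot(inherits(config, "msd_config"))
  slice <- as.matrix(slice)
  if (length(slice) == 0L) stop("'slice' must be nonempty")
  storage.mode(slice) <- "double"
  lay <- param_layout(config)
  if (length(params) != lay$total)
    stop(sprintf("expected %d parameters, got %d", lay$total, length(params)))
  res <- cpp_msd_forward(slice, as.numeric(params), config$depth,
                         config$dilation_cycle, keep_stack)
  prob <- res$prob
  class(prob) <- "prob_map"
  if (!keep_stack) return(prob)
  st <- res$stack
  stack <- lapply(seq_len(dim(st)[3L]), function(i) st[, , i])
  list(prob = prob, stack = stack)
}

#' Run an MS-D network on every axial slice of a volume
#'
#' Slices are independent: slice `k` of the output equals
#' `forward_slice(volume[, , k], ...)` restricted to the bone channel.
#'
#' @param volume 3D numeric array, axial slices along the third index.
#' @inheritParams forward_slice
#' @return 3D array of bone probabilities, same shape as `volume`.
#' @export
forward_volume <- function(volume, params, config) {
  stopifnot(inherits(config, "msd_config"))
  volume <- as_volume3d(volume)
  lay <- param_layout(config)
  if (length(params) != lay$total)
    stop(sprintf("expected %d parameters, got %d", lay$total, length(params)))
  cpp_msd_predict(volume, as.numeric(params), config$depth,
                  config$dilation_cycle)
}

# Accept a matrix as a single-slice volume.
as_volume3d <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("expected a 3D array (or a single slice)")
  storage.mode(x) <- "double"
  x
}

#' Binarize a bone-probability map
#'
#' A pixel is labeled bone iff its bone probability is greater than or equal
#' to `cutoff` (ties go to bone, so raising the cutoff never adds bone
#' pixels).
#'
#' @param prob A `"prob_map"` from [forward_slice()], or a plain array/matrix
#'   of bone probabilities.
#' @param cutoff Threshold strictly inside (0, 1).
#' @return Integer array of 0/1 labels (1 = bone) with the spatial shape of
#'   the input.
#' @export
binarize <- function(prob, cutoff = 0.7) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff <= 0 || cutoff >= 1)
    stop("'cutoff' must lie strictly between 0 and 1")
  bone <- bone_probability(prob)
  out <- array(0L, dim = dim(bone) %||% length(bone))
  out[bone >= cutoff] <- 1L
  dim(out) <- dim(bone)
  out
}

bone_probability <- function(prob) {
  if (inherits(prob, "prob_map")) {
    d <- dim(prob)
    return(array(prob[, , 2L], dim = d[1:2]))
  }
  unclass(prob)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("MS-D probability map: %d x %d pixels, 2 classes\n",
              d[1L], d[2L]))
  cat(sprintf("  bone probability: min %.3f, mean %.3f, max %.3f\n",
              min(x[, , 2L]), mean(x[, , 2L]), max(x[, , 2L])))
  invisible(x)
}
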