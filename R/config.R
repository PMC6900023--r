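#' Mixed-scale dense network configuration
#'
#' Describes the architecture of a mixed-scale dense (MS-D) segmentation
#' network: a stack of `depth` densely connected convolutional layers, each
#' producing one feature map with a 3x3 dilated convolution whose dilation
#' cycles through `1:dilation_cycle` with the layer index, followed by a
#' two-class (background/bone) 1x1 softmax output. The clinical-scale
#' configuration uses 100 layers and a probability cutoff of 0.7; smaller
#' depths train in seconds on desk-scale slices.
#'
#' @param depth Integer number of hidden convolutional layers (>= 0).
#' @param dilation_cycle Integer period of the cyclic dilation schedule
#'   (default 10): layer `i` uses dilation `((i - 1) %% dilation_cycle) + 1`.
#' @param cutoff Probability threshold in (0, 1) used to binarize the bone
#'   probability map (default 0.7).
#' @param width Feature maps per layer; fixed at 1.
#' @param in_channels Input channels; fixed at 1 (grayscale slices).
#' @param num_classes Output classes; fixed at 2 (background, bone).
#' @return An object of class `"msd_config"`.
#' @examples
#' cfg <- msd_config(depth = 100)
#' count_parameters(cfg)
#' @export
msd_config <- function(depth = 100L, dilation_cycle = 10L, cutoff = 0.7,
                       width = 1L, in_channels = 1L, num_classes = 2L) {
  depth <- as.integer(depth)
  dilation_cycle <- as.integer(dilation_cycle)
  if (is.na(depth) || depth < 0L)
    stop("'depth' must be a nonnegative integer")
  if (is.na(dilation_cycle) || dilation_cycle < 1L)
    stop("'dilation_cycle' must be a positive integer")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    stop("'cutoff' must lie strictly between 0 and 1")
  if (width != 1L)
    stop("only width 1 is supported")
  if (in_channels != 1L)
    stop("only single-channel input is supported")
  if (num_classes != 2L)
    stop("only two-class (background/bone) output is supported")
  structure(
    list(depth = depth, dilation_cycle = dilation_cycle, cutoff = cutoff,
         width = 1L, in_channels = 1L, num_classes = 2L, kernel_size = 3L),
    class = "msd_config")
}

#' @export
print.msd_config <- function(x, ...) {
  cat("MS-D network configuration\n")
  cat(sprintf("  depth: %d layers (width 1, 3x3 kernels)\n", x$depth))
  cat(sprintf("  dilation schedule: 1..%d, cyclic\n", x$dilation_cycle))
  cat(sprintf("  output: 2-class softmax, cutoff %.2f\n", x$cutoff))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of an MS-D network
#'
#' Counts every scalar of the parameterization: for hidden layer `i`
#' (1-based), one 3x3 kernel per source map `j = 0..i-1` plus one bias; for
#' the output layer, one 1x1 weight per class per feature map (input map
#' included) plus one bias per class. With width 1, one input channel and two
#' classes this gives `9 d(d+1)/2 + d + 2(d+1) + 2`; depth 100 yields 45,754.
#'
#' @param config An [msd_config()].
#' @return Integer scalar count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "msd_config"))
  d <- config$depth
  wdt <- config$width
  cin <- config$in_channels
  k <- config$kernel_size^2
  hidden <- 0L
  if (d > 0L)
    hidden <- sum(k * wdt * (cin + wdt * (seq_len(d) - 1L)) + wdt)
  out <- config$num_classes * (cin + d * wdt) + config$num_classes
  as.integer(hidden + out)
}

# Offsets into the flat parameter vector (0-based, mirroring the C++ layout).
param_layout <- function(config) {
  d <- config$depth
  K <- as.integer(9 * d * (d + 1) / 2)
  W <- K + d
  B <- W + 2L * (d + 1L)
  list(d = d, kernels = 0L, biases = K, out_weights = W, out_biases = B,
       total = B + 2L)
}

#' Decompose a flat MS-D parameter vector
#'
#' Splits the flat parameter vector used by the training engine into its
#' structured pieces: a list of per-layer kernel lists (`kernels[[i]][[j]]` is
#' the 3x3 kernel applied to source map `j - 1` in layer `i`), the hidden
#' biases, the 2 x (depth + 1) output weight matrix (rows: background, bone)
#' and the two output biases.
#'
#' @param params Numeric vector of length `count_parameters(config)`.
#' @param config An [msd_config()].
#' @return A list with elements `kernels`, `biases`, `out_weights`,
#'   `out_biases`.
#' @export
structure_parameters <- function(params, config) {
  lay <- param_layout(config)
  if (length(params) != lay$total)
    stop(sprintf("expected %d parameters, got %d", lay$total, length(params)))
  d <- lay$d
  kernels <- vector("list", d)
  pos <- 1L
  for (i in seq_len(d)) {
    kernels[[i]] <- lapply(seq_len(i), function(j) {
      k <- matrix(params[pos + (j - 1L) * 9L + 0:8], 3L, 3L, byrow = TRUE)
      dimnames(k) <- list(dr = c("-1", "0", "+1"), dc = c("-1", "0", "+1"))
      k
    })
    pos <- pos + 9L * i
  }
  biases <- params[lay$biases + seq_len(d)]
  ow <- matrix(params[lay$out_weights + seq_len(2L * (d + 1L))],
               nrow = 2L, byrow = TRUE,
               dimnames = list(class = c("background", "bone"), map = 0:d))
  ob <- params[lay$out_biases + 1:2]
  names(ob) <- c("background", "bone")
  list(kernels = kernels, biases = biases, out_weights = ow, out_biases = ob)
}

# Inverse of structure_parameters(); used by tests and checkpoint I/O.
flatten_parameters <- function(str, config) {
  lay <- param_layout(config)
  out <- numeric(lay$total)
  pos <- 1L
  for (i in seq_len(lay$d)) {
    for (j in seq_len(i)) {
      out[pos:(pos + 8L)] <- as.vector(t(str$kernels[[i]][[j]]))
      pos <- pos + 9L
    }
  }
  if (lay$d > 0L)
    out[lay$biases + seq_len(lay$d)] <- str$biases
  out[lay$out_weights + seq_len(2L * (lay$d + 1L))] <- as.vector(t(str$out_weights))
  out[lay$out_biases + 1:2] <- str$out_biases
  out
}
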