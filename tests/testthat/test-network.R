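test_that("dilation schedule starts at 1, steps by 1 and resets after a cycle", {
  expect_identical(dilation_for_layer(1L), 1L)
  expect_identical(dilation_for_layer(11L), 1L)
  expect_identical(dilation_for_layer(25L), 5L)
  expect_identical(dilation_for_layer(1:20), rep(1:10, 2L))
  expect_true(all(dilation_for_layer(1:100, cycle = 7L) <= 7L))
  expect_error(dilation_for_layer(0L), "index")
  expect_error(dilation_for_layer(1L, cycle = 0L), "cycle")
})

test_that("dilated convolution is exact against a naive reflected-index oracle", {
  set.seed(42)
  for (case in 1:25) {
    h <- sample(5:21, 1L)
    w <- sample(5:21, 1L)
    s <- sample(1:10, 1L)
    map <- matrix(rnorm(h * w), h, w)
    ker <- matrix(rnorm(9), 3L, 3L)
    expect_lt(max(abs(dilated_conv(map, ker, s) -
                        naive_dilated_conv(map, ker, s))), 1e-10)
  }
})

test_that("dilated convolution handles constant maps, identity kernels and bad input", {
  v <- 2.5
  ones <- matrix(1, 3L, 3L)
  for (s in c(1L, 3L, 9L))
    expect_equal(dilated_conv(matrix(v, 6L, 7L), ones, s),
                 matrix(9 * v, 6L, 7L))
  ident <- matrix(0, 3L, 3L)
  ident[2L, 2L] <- 1
  m <- matrix(rnorm(30), 5L, 6L)
  expect_equal(dilated_conv(m, ident, 4L), m)
  expect_error(dilated_conv(m, ident, 0L), "dilation")
  expect_error(dilated_conv(matrix(numeric(0), 0L, 0L), ident, 1L), "nonempty")
})

test_that("hidden layers sum per-map convolutions, add bias and rectify", {
  z <- matrix(0, 4L, 4L)
  k <- list(matrix(rnorm(9), 3L, 3L))
  expect_equal(layer_forward(list(z), k, bias = -1, dilation = 1L),
               matrix(0, 4L, 4L))
  expect_equal(layer_forward(list(matrix(rnorm(16), 4L, 4L)),
                             list(matrix(0, 3L, 3L)), bias = 2, dilation = 1L),
               matrix(2, 4L, 4L))
  set.seed(7)
  z1 <- matrix(rnorm(49), 7L, 7L)
  z2 <- matrix(rnorm(49), 7L, 7L)
  k1 <- matrix(rnorm(9), 3L, 3L)
  k2 <- matrix(rnorm(9), 3L, 3L)
  want <- pmax(naive_dilated_conv(z1, k1, 2L) +
                 naive_dilated_conv(z2, k2, 2L) + 0.3, 0)
  expect_equal(layer_forward(list(z1, z2), list(k1, k2), 0.3, 2L), want,
               tolerance = 1e-12)
  expect_error(layer_forward(list(z1, z2), list(k1), 0, 1L), "kernels")
})

test_that("softmax output is symmetric at zero weights and matches closed form", {
  stack <- list(matrix(rnorm(20), 4L, 5L), matrix(rnorm(20), 4L, 5L))
  p <- output_probabilities(stack, matrix(0, 2L, 2L), c(0, 0))
  expect_equal(as.numeric(p), rep(0.5, 40L))
  # a logit difference of log(3) puts probability 3/4 on bone
  one <- list(matrix(1, 2L, 2L))
  p3 <- output_probabilities(one, matrix(c(0, log(3)), 2L, 1L), c(0, 0))
  expect_equal(as.numeric(p3[, , 2L]), rep(0.75, 4L), tolerance = 1e-12)
  # normalization holds for arbitrary weights
  set.seed(1)
  pr <- output_probabilities(stack, matrix(rnorm(4), 2L, 2L), rnorm(2))
  expect_lt(max(abs(pr[, , 1L] + pr[, , 2L] - 1)), 1e-6)
  expect_true(all(pr >= 0))
  expect_error(output_probabilities(stack, matrix(0, 2L, 3L), c(0, 0)),
               "weights")
})

test_that("forward_slice composes the layer recurrence and the output layer", {
  cfg <- msd_config(depth = 3L, dilation_cycle = 2L, cutoff = 0.5)
  set.seed(11)
  params <- init_parameters(cfg, 11L) + rnorm(count_parameters(cfg), sd = 0.2)
  x <- matrix(rnorm(25), 5L, 5L)
  str <- structure_parameters(params, cfg)
  stack <- list(x)
  for (i in 1:3) {
    s <- dilation_for_layer(i, cfg$dilation_cycle)
    zi <- 0
    for (j in seq_len(i))
      zi <- zi + naive_dilated_conv(stack[[j]], str$kernels[[i]][[j]], s)
    stack[[i + 1L]] <- pmax(zi + str$biases[i], 0)
  }
  want <- output_probabilities(stack, str$out_weights, str$out_biases)
  got <- forward_slice(x, params, cfg, keep_stack = TRUE)
  expect_equal(unclass(got$prob), unclass(want), tolerance = 1e-10)
  expect_equal(got$stack, stack, tolerance = 1e-10)
  # deterministic
  expect_identical(forward_slice(x, params, cfg), forward_slice(x, params, cfg))
  # depth-0 network with zero output weights is uniform
  cfg0 <- msd_config(depth = 0L)
  expect_equal(as.numeric(forward_slice(x, numeric(4L), cfg0)), rep(0.5, 50L))
})

test_that("feature maps and outputs preserve the input shape at every depth", {
  for (depth in c(0L, 1L, 4L, 12L)) {
    cfg <- msd_config(depth = depth, cutoff = 0.5)
    params <- init_parameters(cfg, depth + 1L)
    out <- forward_slice(matrix(rnorm(7 * 9), 7L, 9L), params, cfg,
                         keep_stack = TRUE)
    expect_true(all(vapply(out$stack, function(z)
      identical(dim(z), c(7L, 9L)), logical(1))))
    expect_identical(dim(out$prob), c(7L, 9L, 2L))
    expect_lt(max(abs(out$prob[, , 1L] + out$prob[, , 2L] - 1)), 1e-6)
  }
})

test_that("binarize labels ties as bone and is monotone in the cutoff", {
  p <- matrix(c(1.0, 0.69, 0.5, 0.71), 2L, 2L)
  expect_identical(binarize(p, 0.7), array(c(1L, 0L, 0L, 1L), dim = c(2L, 2L)))
  expect_identical(binarize(matrix(0.5, 3L, 3L), 0.5),
                   array(1L, dim = c(3L, 3L)))
  set.seed(3)
  pm <- matrix(runif(100), 10L, 10L)
  cuts <- sort(runif(10, 0.05, 0.95))
  counts <- vapply(cuts, function(ct) sum(binarize(pm, ct)), integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_error(binarize(pm, 0), "cutoff")
  expect_error(binarize(pm, 1), "cutoff")
})

test_that("parameter count equals exhaustive enumeration of the tensors", {
  for (depth in c(0L, 1L, 3L, 10L)) {
    cfg <- msd_config(depth = depth)
    str <- structure_parameters(init_parameters(cfg, 1L), cfg)
    n_enum <- length(unlist(str$kernels)) + length(str$biases) +
      length(str$out_weights) + length(str$out_biases)
    expect_identical(count_parameters(cfg), as.integer(n_enum))
  }
  expect_identical(count_parameters(msd_config(depth = 0L)), 4L)
  expect_identical(count_parameters(msd_config(depth = 3L)), 67L)
  expect_identical(count_parameters(msd_config(depth = 100L)), 45754L)
})

test_that("parameter structuring and flattening are mutually inverse", {
  cfg <- msd_config(depth = 6L)
  p <- init_parameters(cfg, 2L) + seq_len(count_parameters(cfg)) * 1e-4
  str <- structure_parameters(p, cfg)
  expect_equal(msdseg:::flatten_parameters(str, cfg), p)
  expect_error(structure_parameters(p[-1L], cfg), "expected")
})

test_that("volumes are segmented slice by slice, independently", {
  cfg <- msd_config(depth = 2L, cutoff = 0.5)
  params <- init_parameters(cfg, 4L) + 0.05
  vol <- array(rnorm(6 * 6 * 3), dim = c(6L, 6L, 3L))
  out <- forward_volume(vol, params, cfg)
  expect_identical(dim(out), dim(vol))
  for (k in 1:3) {
    pk <- forward_slice(vol[, , k], params, cfg)
    expect_equal(out[, , k], pk[, , 2L], tolerance = 1e-14)
  }
  # permuting slices permutes outputs identically
  perm <- c(3L, 1L, 2L)
  expect_equal(forward_volume(vol[, , perm], params, cfg), out[, , perm])
  # a single-slice volume equals forward_slice
  v1 <- array(vol[, , 1L], dim = c(6L, 6L, 1L))
  expect_equal(forward_volume(v1, params, cfg)[, , 1L],
               forward_slice(vol[, , 1L], params, cfg)[, , 2L])
})
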