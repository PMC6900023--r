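test_that("normalization pools all training voxels and rejects constant data", {
  stats <- compute_normalization(list(array(0, c(1, 2, 1)),
                                      array(2, c(1, 2, 1))))
  expect_equal(stats$mean, 1)
  expect_equal(stats$sd, 1)
  expect_error(compute_normalization(array(5, c(2, 2, 2))), "degenerate")
  # z-score identity: applying a volume's own stats gives mean 0, sd 1
  set.seed(1)
  v <- array(rnorm(200, 4, 3), c(10, 10, 2))
  z <- apply_normalization(v, compute_normalization(v))
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  # round trip
  st <- compute_normalization(v)
  expect_equal(apply_normalization(apply_normalization(v, st), st,
                                   invert = TRUE), v, tolerance = 1e-9)
  # identity stats
  st1 <- structure(list(mean = 0, sd = 1), class = "norm_stats")
  expect_identical(apply_normalization(v, st1), v)
})

test_that("training statistics are fit on training volumes only", {
  set.seed(2)
  train <- list(array(rnorm(64, 1), c(4, 4, 4)))
  test_vol <- array(rnorm(64, 10), c(4, 4, 4))
  st_train <- compute_normalization(train)
  st_leaky <- compute_normalization(c(train, list(test_vol)))
  expect_gt(abs(st_leaky$mean - st_train$mean), 1)
  fit <- msd_fit(train[[1]], array(rep(0:1, 32), c(4, 4, 4)), depth = 1L,
                 epochs = 1L, seed = 1L)
  expect_equal(fit$stats$mean, st_train$mean)
})

test_that("initialization is seed-reproducible with a zeroed output layer", {
  cfg <- msd_config(depth = 5L)
  p1 <- init_parameters(cfg, 9L)
  p2 <- init_parameters(cfg, 9L)
  expect_identical(p1, p2)
  expect_false(identical(p1, init_parameters(cfg, 10L)))
  str <- structure_parameters(p1, cfg)
  expect_true(all(str$out_weights == 0))
  expect_true(all(str$biases == 0))
  # hence the fresh network is maximally uncertain everywhere
  pr <- forward_slice(matrix(rnorm(64), 8L, 8L), p1, cfg)
  expect_equal(as.numeric(pr), rep(0.5, 128L))
  # kernel scale follows 1/sqrt(fan-in)
  k1 <- unlist(str$kernels[[1L]])
  k5 <- unlist(str$kernels[[5L]])
  expect_lt(sd(k5), sd(k1)) # fan-in grows with depth
})

test_that("init_parameters leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(init_parameters(msd_config(depth = 3L), 7L))
  expect_identical(.Random.seed, before)
})

test_that("a zero learning rate leaves parameters unchanged with a flat loss", {
  set.seed(4)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  y <- array(rbinom(192, 1, 0.4), c(8, 8, 3))
  fit <- msd_fit(x, y, depth = 2L, epochs = 3L, lr = 0, seed = 5L)
  expect_identical(fit$params, init_parameters(fit$config, 5L))
  expect_equal(length(fit$loss), 3L)
  expect_lt(diff(range(fit$loss)), 1e-12)
})

test_that("training reduces the loss on a separable toy problem", {
  for (seed in c(1L, 2L)) {
    set.seed(seed)
    y <- array(0L, c(16, 16, 1))
    y[5:12, 5:12, 1] <- 1L
    x <- array(rnorm(256, sd = 0.3), c(16, 16, 1)) + 2 * y
    fit <- msd_fit(x, y, depth = 5L, epochs = 200L, seed = seed)
    expect_lt(fit$loss[length(fit$loss)], fit$loss[1L])
    expect_lt(fit$loss[length(fit$loss)], 0.1)
  }
})

test_that("an all-background gold mask drives the predicted bone fraction down", {
  set.seed(6)
  x <- array(rnorm(256), c(16, 16, 1))
  y <- array(0L, c(16, 16, 1))
  fit <- msd_fit(x, y, depth = 3L, epochs = 50L, seed = 6L)
  frac <- mean(predict(fit, x[, , 1], type = "prob") >= 0.5)
  expect_lt(frac, 0.05) # started at 1.0 under the >= tie rule
})

test_that("training is deterministic given the seed", {
  set.seed(8)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  y <- array(rbinom(256, 1, 0.3), c(8, 8, 4))
  f1 <- msd_fit(x, y, depth = 3L, epochs = 4L, seed = 2L)
  f2 <- msd_fit(x, y, depth = 3L, epochs = 4L, seed = 2L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss, f2$loss)
  f3 <- msd_fit(x, y, depth = 3L, epochs = 4L, seed = 3L)
  expect_false(identical(f1$params, f3$params))
})

test_that("leave-2-out folds partition the ids into disjoint test pairs", {
  ids <- sprintf("p%02d", 1:18)
  folds <- leave_two_out_folds(ids)
  expect_length(folds, 9L)
  for (f in folds) {
    expect_length(f$test, 2L)
    expect_length(f$train, 16L)
    expect_setequal(c(f$train, f$test), ids)
  }
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tests, ids)
  expect_false(anyDuplicated(tests) > 0L)
  # documented 4-id layout: sorted consecutive pairs
  f4 <- leave_two_out_folds(c("d", "b", "a", "c"))
  expect_identical(f4[[1L]], list(train = c("c", "d"), test = c("a", "b")))
  expect_identical(f4[[2L]], list(train = c("a", "b"), test = c("c", "d")))
  expect_error(leave_two_out_folds(letters[1:5]), "even")
  expect_error(leave_two_out_folds(c("a", "a", "b", "c")), "unique")
})

test_that("fold exhaustiveness holds for any even id count", {
  for (n in c(4L, 6L, 10L, 18L)) {
    folds <- leave_two_out_folds(seq_len(n))
    expect_length(folds, n %/% 2L)
    expect_setequal(unlist(lapply(folds, `[[`, "test")), seq_len(n))
  }
})

test_that("cross-validation yields one row per volume and is seed-reproducible", {
  ds <- fixture("cv_dataset", function()
    generate_dataset(tiny_phantom_spec(), n_volumes = 4L, seed = 3L))
  cfg <- msd_config(depth = 4L, cutoff = 0.5)
  t1 <- run_cross_validation(ds, cfg, epochs = 6L, seed = 2L)
  expect_identical(nrow(t1), 4L)
  expect_setequal(t1$scan_id, vapply(ds, `[[`, character(1), "id"))
  expect_true(all(t1$dice >= 0 & t1$dice <= 1))
  t2 <- run_cross_validation(ds, cfg, epochs = 6L, seed = 2L)
  expect_identical(t1, t2)
  expect_error(run_cross_validation(ds[1:2], cfg), "at least 4")
})

test_that("the grid sweep recovers a planted optimal cutoff", {
  ds <- fixture("cv_dataset", function()
    generate_dataset(tiny_phantom_spec(), n_volumes = 4L, seed = 3L))
  # plant the optimum: the validation gold IS a fixed model's 0.5-binarization
  oracle_fit <- msd_fit(ds[1:3], depth = 4L, epochs = 6L, seed = 2L,
                        cutoff = 0.5)
  val <- lapply(ds[4], function(v) {
    v$bone_mask <- predict(oracle_fit, v$image, type = "mask", cutoff = 0.5)
    v
  })
  sw <- sweep_hyperparameters(ds[1:3], val,
                              hyper_grid(depths = 4L,
                                         cutoffs = c(0.1, 0.3, 0.5, 0.7, 0.9)),
                              epochs = 6L, seed = 2L)
  expect_identical(sw$cutoff, 0.5)
  expect_identical(sw$depth, 4L)
  # a single-entry grid returns that entry
  sw1 <- sweep_hyperparameters(ds[1:3], val,
                               hyper_grid(depths = 2L, cutoffs = 0.3),
                               epochs = 1L, seed = 2L)
  expect_identical(c(sw1$depth, sw1$cutoff), c(2, 0.3))
  # the returned pair is always a grid member
  expect_true(sw$depth %in% c(4L) && sw$cutoff %in% c(0.1, 0.3, 0.5, 0.7, 0.9))
})
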