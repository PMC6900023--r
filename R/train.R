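#' Intensity normalization statistics
#'
#' Pools every voxel of the training volumes and returns their mean and
#' population standard deviation. Test volumes are always normalized with the
#' training-set statistics, never their own.
#'
#' @param volumes A numeric array, or a list of numeric arrays (the training
#'   volumes). Lists of labeled volumes (elements with an `$image` field) are
#'   accepted.
#' @return A list with elements `mean` and `sd`, class `"norm_stats"`.
#' @export
compute_normalization <- function(volumes) {
  vox <- pooled_voxels(volumes)
  if (length(vox) == 0L) stop("no voxels to normalize")
  m <- mean(vox)
  s <- sqrt(mean((vox - m)^2)) # population SD
  if (s == 0) stop("degenerate data: all training voxels are identical")
  structure(list(mean = m, sd = s), class = "norm_stats")
}

pooled_voxels <- function(volumes) {
  if (is.list(volumes) && !is.null(volumes$image)) volumes <- list(volumes)
  if (!is.list(volumes)) volumes <- list(volumes)
  unlist(lapply(volumes, function(v) {
    if (is.list(v) && !is.null(v$image)) v <- v$image
    as.numeric(v)
  }), use.names = FALSE)
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("normalization: mean %.4g, sd %.4g\n", x$mean, x$sd))
  invisible(x)
}

#' Apply (or invert) intensity normalization
#'
#' @param volume Numeric array or matrix.
#' @param stats A `"norm_stats"` object from [compute_normalization()].
#' @param invert If `TRUE`, undo the transform (`v * sd + mean`).
#' @return The transformed array, same shape.
#' @export
apply_normalization <- function(volume, stats, invert = FALSE) {
  stopifnot(inherits(stats, "norm_stats"))
  if (invert) volume * stats$sd + stats$mean
  else (volume - stats$mean) / stats$sd
}

#' Seeded initialization of MS-D parameters
#'
#' Hidden 3x3 kernels are drawn from a zero-mean normal with standard
#' deviation `1 / sqrt(fan_in)` (layer `i` has fan-in `9 i` taps).
#' All biases and every output weight start at zero, so a freshly initialized
#' network outputs probability 0.5 everywhere. Fully reproducible from
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param config An [msd_config()].
#' @param seed Integer seed.
#' @return Flat numeric parameter vector of length
#'   `count_parameters(config)`.
#' @export
init_parameters <- function(config, seed = 1L) {
  stopifnot(inherits(config, "msd_config"))
  lay <- param_layout(config)
  params <- numeric(lay$total)
  with_seed(seed, {
    pos <- 1L
    for (i in seq_len(lay$d)) {
      n <- 9L * i
      params[pos:(pos + n - 1L)] <- rnorm(n, sd = sqrt(1 / n))
      pos <- pos + n
    }
  })
  params
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Per-epoch visiting orders: reshuffled every epoch from a seed derived from
# (seed, epoch), truncated to max_steps total steps.
slice_order <- function(n_slices, epochs, seed, max_steps = NULL) {
  orders <- unlist(lapply(seq_len(epochs), function(e) {
    with_seed(seed + 100003L * e, sample.int(n_slices))
  }))
  if (!is.null(max_steps) && length(orders) > max_steps)
    orders <- orders[seq_len(max_steps)]
  orders
}

# Core batch-size-1 Adam engine over a slice cube; returns updated params and
# per-step losses.
train_engine <- function(slices, masks, params, config, epochs, seed,
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         max_steps = NULL) {
  n <- dim(slices)[3L]
  order <- slice_order(n, epochs, seed, max_steps)
  res <- cpp_msd_train(slices, masks, as.numeric(params), config$depth,
                       config$dilation_cycle, as.integer(order - 1L),
                       lr, beta1, beta2, eps)
  steps_per_epoch <- n
  epoch_id <- ((seq_along(res$losses) - 1L) %/% steps_per_epoch) + 1L
  list(params = res$params,
       step_losses = as.numeric(res$losses),
       epoch_losses = as.numeric(tapply(res$losses, epoch_id, mean)))
}

#' Leave-2-out fold plan
#'
#' Sorts the scan ids, groups them into consecutive disjoint pairs, and
#' builds one fold per pair: the pair is the test set, all remaining ids the
#' training set. With 18 scans this yields 9 folds of 16 train / 2 test.
#'
#' @param ids Vector of scan identifiers (even length >= 4).
#' @return A list of folds, each `list(train = ..., test = ...)`; class
#'   `"fold_plan"`.
#' @export
leave_two_out_folds <- function(ids) {
  if (anyDuplicated(ids)) stop("scan ids must be unique")
  n <- length(ids)
  if (n < 4L || n %% 2L != 0L)
    stop("leave-2-out needs an even number of ids, at least 4")
  ids <- sort(ids)
  folds <- lapply(seq_len(n %/% 2L), function(k) {
    test <- ids[c(2L * k - 1L, 2L * k)]
    list(train = setdiff(ids, test), test = test)
  })
  structure(folds, class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("leave-2-out plan: %d folds\n", length(x)))
  for (k in seq_along(x))
    cat(sprintf("  fold %d: test {%s}\n", k, paste(x[[k]]$test, collapse = ", ")))
  invisible(x)
}

#' Leave-2-out cross-validation of an MS-D network
#'
#' For every fold: normalization statistics are fitted on the training
#' volumes only, a network is trained from scratch, the held-out volumes are
#' segmented at the configured cutoff, and their Dice coefficients recorded.
#'
#' @param dataset A list of labeled volumes as produced by
#'   [generate_dataset()]: each element has `$image`, `$bone_mask` and `$id`.
#' @param config An [msd_config()].
#' @param epochs Training epochs per fold.
#' @param seed Integer seed controlling initialization and slice shuffling.
#' @param ... Further arguments passed to [msd_fit()] (e.g. `lr`,
#'   `max_steps`).
#' @return A `data.frame` with columns `scan_id`, `method`, `dice` (one row
#'   per volume), ordered by fold.
#' @export
run_cross_validation <- function(dataset, config, epochs = 10L, seed = 1L,
                                 ...) {
  if (length(dataset) < 4L) stop("cross-validation needs at least 4 volumes")
  ids <- vapply(dataset, function(v) as.character(v$id), character(1))
  names(dataset) <- ids
  folds <- leave_two_out_folds(ids)
  rows <- list()
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    fit <- msd_fit(dataset[fold$train], depth = config$depth,
                   dilation_cycle = config$dilation_cycle,
                   cutoff = config$cutoff, epochs = epochs,
                   seed = seed + k, ...)
    for (id in fold$test) {
      mask <- predict(fit, dataset[[id]]$image, type = "mask")
      d <- dice(confusion(mask, dataset[[id]]$bone_mask))
      rows[[length(rows) + 1L]] <-
        data.frame(scan_id = id, method = "msd", dice = d,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Hyper-parameter grid
#'
#' The default grid spans network depths 30-150 and binarization cutoffs
#' 0.1-0.9 (step 0.2).
#'
#' @param depths Integer vector of candidate depths.
#' @param cutoffs Numeric vector of candidate cutoffs in (0, 1).
#' @return A list with elements `depths` and `cutoffs`, class `"hyper_grid"`.
#' @export
hyper_grid <- function(depths = c(30L, 50L, 80L, 100L, 150L),
                       cutoffs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(depths) == 0L || length(cutoffs) == 0L)
    stop("grid must be nonempty")
  structure(list(depths = as.integer(depths), cutoffs = cutoffs),
            class = "hyper_grid")
}

#' Grid search over depth and cutoff on held-out validation scans
#'
#' Trains one network per candidate depth on the training volumes, then
#' evaluates the mean validation Dice at every candidate cutoff (the cutoff
#' only affects binarization, so it is swept without retraining). Returns the
#' maximizing pair; ties are broken toward the smaller depth, then the
#' smaller cutoff.
#'
#' @param train_data,validation_data Lists of labeled volumes (see
#'   [generate_dataset()]).
#' @param grid A [hyper_grid()].
#' @param epochs,seed,... Passed to [msd_fit()].
#' @return `list(depth =, cutoff =, scores =)` where `scores` is a
#'   `data.frame` of mean validation Dice per grid point.
#' @export
sweep_hyperparameters <- function(train_data, validation_data,
                                  grid = hyper_grid(), epochs = 10L,
                                  seed = 1L, ...) {
  stopifnot(inherits(grid, "hyper_grid"))
  if (length(validation_data) == 0L) stop("validation set is empty")
  scores <- list()
  for (depth in grid$depths) {
    fit <- msd_fit(train_data, depth = depth, epochs = epochs, seed = seed,
                   ...)
    probs <- lapply(validation_data,
                    function(v) predict(fit, v$image, type = "prob"))
    for (cutoff in grid$cutoffs) {
      ds <- mapply(function(p, v) {
        dice(confusion(binarize(p, cutoff), v$bone_mask))
      }, probs, validation_data)
      scores[[length(scores) + 1L]] <-
        data.frame(depth = depth, cutoff = cutoff, mean_dice = mean(ds))
    }
  }
  scores <- do.call(rbind, scores)
  # maximize mean Dice; ties -> smaller depth, then smaller cutoff
  ord <- order(-scores$mean_dice, scores$depth, scores$cutoff)
  best <- scores[ord[1L], ]
  list(depth = best$depth, cutoff = best$cutoff, scores = scores)
}
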