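test_that("phantom slices are deterministic with exact, disjoint masks", {
  spec <- phantom_spec(size = 48L, n_slices = 4L, metal_count = 2L, seed = 5L)
  a <- generate_slice_phantom(spec, 2L)
  b <- generate_slice_phantom(spec, 2L)
  expect_identical(a, b)
  expect_true(sum(a$metal_mask) > 0L)
  expect_identical(sum(a$bone_mask * a$metal_mask), 0L) # disjoint
  att <- spec$attenuation
  expect_true(all(a$image[a$metal_mask == 1L] == att[["metal"]]))
  expect_true(all(a$image[a$bone_mask == 1L] == att[["bone"]]))
  # no metal requested -> empty metal mask
  spec0 <- phantom_spec(size = 48L, metal_count = 0L)
  expect_identical(sum(generate_slice_phantom(spec0, 1L)$metal_mask), 0L)
  expect_error(generate_slice_phantom(spec, 9L), "slice range")
  expect_error(phantom_spec(size = 48L, arch_radius = 40), "fit")
})

test_that("bone area is stable under the per-volume geometry jitter", {
  spec <- phantom_spec(size = 48L, n_slices = 1L, metal_count = 1L)
  counts <- vapply(1:20, function(s) {
    js <- msdseg:::jitter_spec(spec, s)
    sum(generate_slice_phantom(js, 1L)$bone_mask)
  }, numeric(1))
  expect_lt(max(counts) / mean(counts), 1.2)
  expect_gt(min(counts) / mean(counts), 0.8)
})

test_that("forward projection conserves mass and respects rotational symmetry", {
  pars <- sinogram_params(size = 48L, n_angles = 36L)
  expect_equal(radon_project(matrix(0, 48L, 48L), pars),
               matrix(0, 36L, pars$n_bins))
  # centered disk (area-sampled edge so the object itself is rotationally
  # symmetric): every angle sees the same profile
  sub <- (seq_len(4L) - 0.5) / 4 - 0.5
  disk <- matrix(0, 48L, 48L)
  for (oi in sub) for (oj in sub) {
    x <- matrix(rep(0:47 + oi, each = 48L), 48L, 48L)
    y <- t(matrix(rep(0:47 + oj, each = 48L), 48L, 48L))
    disk <- disk + ((x - 23.5)^2 + (y - 23.5)^2 <= 12^2)
  }
  disk <- disk / 16 * 0.05
  sino <- radon_project(disk, pars, spacing = 0.2)
  peak <- max(sino)
  dev <- apply(sino, 2L, function(col) diff(range(col)))
  expect_lt(max(dev), 0.02 * peak)
  # per-angle mass: sum over bins ~ map sum x spacing
  expect_equal(mean(rowSums(sino)), sum(disk) * 0.2, tolerance = 0.01)
  expect_error(radon_project(matrix(0, 3L, 4L), pars), "square")
})

test_that("photon statistics reduce to the identity without noise or hardening", {
  pars <- sinogram_params(size = 32L, alpha = 0)
  sino <- matrix(runif(16, 0, 3), 4L, 4L)
  out <- apply_photon_statistics(sino, pars, noise = FALSE)
  expect_equal(out, sino, tolerance = 1e-6)
})

test_that("photon starvation clamps saturated rays at log(I0)", {
  pars <- sinogram_params(size = 32L, alpha = 0, I0 = 1e5)
  sino <- matrix(c(0.5, 40, 13, 0), 2L, 2L) # 40 and 13 starve: I0 e^-p < 1
  out <- apply_photon_statistics(sino, pars, noise = FALSE)
  expect_identical(out[c(2L, 3L)], rep(log(1e5), 2L))
  expect_lt(abs(out[1L] - 0.5), 1e-6)
  # seeded runs reproduce
  r1 <- msdseg:::with_seed(3L, apply_photon_statistics(sino, pars))
  r2 <- msdseg:::with_seed(3L, apply_photon_statistics(sino, pars))
  expect_identical(r1, r2)
})

test_that("filtered back-projection is linear and inverts the projection", {
  pars <- sinogram_params(size = 48L, n_angles = 60L)
  zero <- fbp_reconstruct(matrix(0, 60L, pars$n_bins), pars, size = 48L)
  expect_equal(zero, matrix(0, 48L, 48L))
  x <- matrix(rep(0:47, each = 48L), 48L, 48L)
  y <- t(x)
  disk <- exp(-((x - 23.5)^2 + (y - 23.5)^2) / (2 * 9^2)) * 0.05
  sino <- radon_project(disk, pars, spacing = 0.2)
  rec <- fbp_reconstruct(sino, pars, size = 48L, spacing = 0.2)
  supp <- disk > 0.1 * max(disk)
  rel_rmse <- sqrt(mean((rec[supp] - disk[supp])^2)) /
    sqrt(mean(disk[supp]^2))
  expect_lt(rel_rmse, 0.10)
  # linearity
  expect_equal(fbp_reconstruct(3.5 * sino, pars, size = 48L, spacing = 0.2),
               3.5 * rec, tolerance = 1e-9)
  expect_error(fbp_reconstruct(matrix(0, 10L, 10L), pars), "shape")
})

test_that("dataset generation is reproducible and labels ignore the artifacts", {
  spec <- tiny_phantom_spec()
  d1 <- generate_dataset(spec, n_volumes = 2L, seed = 11L)
  d2 <- generate_dataset(spec, n_volumes = 2L, seed = 11L)
  expect_identical(d1, d2)
  expect_identical(dim(d1[[1L]]$image), c(32L, 32L, 2L))
  # paired metal-off volume, same seed: identical geometry and labels
  d0 <- generate_dataset(spec, n_volumes = 2L, seed = 11L, metal = FALSE)
  expect_identical(d0[[1L]]$bone_mask, d1[[1L]]$bone_mask)
  expect_identical(d0[[1L]]$metal_mask, d1[[1L]]$metal_mask)
})

test_that("metal inclusions strictly increase out-of-metal intensity variance", {
  spec <- tiny_phantom_spec(metal = 2L, size = 48L)
  with_m <- generate_dataset(spec, n_volumes = 1L, seed = 21L)[[1L]]
  without <- generate_dataset(spec, n_volumes = 1L, seed = 21L,
                              metal = FALSE)[[1L]]
  out_of_metal <- with_m$metal_mask == 0L & with_m$bone_mask == 0L
  expect_gt(var(with_m$image[out_of_metal]), var(without$image[out_of_metal]))
})

test_that("a clean reconstruction matches the phantom up to the noise floor", {
  spec <- tiny_phantom_spec(metal = 0L)
  noisy <- generate_dataset(spec, n_volumes = 1L, seed = 31L)[[1L]]
  clean <- generate_dataset(spec, n_volumes = 1L, seed = 31L,
                            corrupt = FALSE)[[1L]]
  expect_identical(noisy$bone_mask, clean$bone_mask)
  # without metal the noise perturbation is small
  expect_lt(mean(abs(noisy$image - clean$image)), 0.005)
})

test_that("global thresholding degrades on corrupted volumes", {
  spec <- phantom_spec(size = 48L, n_slices = 2L, metal_count = 2L, seed = 5L)
  spec0 <- phantom_spec(size = 48L, n_slices = 2L, metal_count = 0L, seed = 5L)
  corrupted <- generate_dataset(spec, n_volumes = 1L, seed = 41L)[[1L]]
  clean <- generate_dataset(spec0, n_volumes = 1L, seed = 41L,
                            corrupt = FALSE)[[1L]]
  d_cor <- best_threshold_dice(corrupted$image, corrupted$bone_mask)$dice
  d_cln <- best_threshold_dice(clean$image, clean$bone_mask)$dice
  expect_gt(d_cln, d_cor)
  expect_gt(d_cln, 0.9)
})
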