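# Independent oracles and shared fixtures for the test suite.

# Reflection oracle: mirror about the border pixel (0-based index).
reflect_oracle <- function(x, n) {
  if (n == 1) return(0L)
  p <- 2L * (n - 1L)
  x <- x %% p
  if (x >= n) x <- p - x
  x
}

# Naive triple-loop dilated convolution with explicit reflected indexing.
naive_dilated_conv <- function(map, ker, s) {
  h <- nrow(map)
  w <- ncol(map)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 0
    for (a in -1:1) for (b in -1:1)
      acc <- acc + ker[a + 2L, b + 2L] *
        map[reflect_oracle(r - 1L + s * a, h) + 1L,
            reflect_oracle(c - 1L + s * b, w) + 1L]
    out[r, c] <- acc
  }
  out
}

# Set-wise Dice oracle: 2|A∩B| / (|A| + |B|).
setwise_dice <- function(a, b) {
  a <- which(as.logical(a))
  b <- which(as.logical(b))
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Edge table of a mesh: each row one undirected edge key.
mesh_edge_keys <- function(mesh) {
  ed <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
              mesh$triangles[, c(3, 1)])
  ed <- t(apply(ed, 1L, sort))
  paste(ed[, 1L], ed[, 2L])
}

# Voxel ball mask of radius r (voxels) centered in a cube grid.
ball_mask <- function(r, n = 2L * r + 5L) {
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  out <- array(0L, dim = c(n, n, n))
  out[idx[rowSums((idx - ctr)^2) <= r^2, ]] <- 1L
  out
}

# Small, easy phantom settings shared by the slower tests.
tiny_phantom_spec <- function(metal = 1L, seed = 3L, size = 32L,
                              n_slices = 2L) {
  phantom_spec(size = size, n_slices = n_slices, metal_count = metal,
               seed = seed, arch_radius = 0.26 * size,
               tooth_radius = 0.045 * size, n_teeth = 5L)
}

# Memoized fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}
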