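#' Triangle mesh in mm coordinates
#'
#' A surface as a vertex table plus vertex-index triples. Per-triangle unit
#' normals follow the right-hand rule on the vertex order, so a consistently
#' wound mesh has outward normals and a positive enclosed volume.
#'
#' @param vertices Numeric `n x 3` matrix (mm).
#' @param triangles Integer `t x 3` matrix of 1-based vertex indices.
#' @return Object of class `"triangle_mesh"` with components `vertices`,
#'   `triangles`, `normals`.
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 normals = face_normals(vertices, triangles)),
            class = "triangle_mesh")
}

face_normals <- function(vertices, triangles) {
  if (nrow(triangles) == 0L)
    return(matrix(numeric(0), 0L, 3L))
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c_ <- vertices[triangles[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  n <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  len <- sqrt(rowSums(n^2))
  if (any(len == 0)) stop("degenerate (zero-area) triangle")
  n / len
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  if (nrow(x$triangles) > 0L)
    cat(sprintf("  enclosed volume: %.3f mm^3\n", mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin); positive for watertight meshes with outward-wound triangles.
#'
#' @param mesh A `"triangle_mesh"`.
#' @return Numeric scalar in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$triangles) == 0L) return(0)
  a <- mesh$vertices[mesh$triangles[, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2L], , drop = FALSE]
  c_ <- mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]
  cr <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
              b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
              b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(rowSums(a * cr)) / 6
}

# The six tetrahedra of the Kuhn subdivision of the unit cube: corner 0,
# then a monotone axis path to corner 7. Identical in every cube, so shared
# cube faces are split along the same diagonals and the isosurface is
# watertight.
kuhn_tets <- function() {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  lapply(perms, function(p) {
    v <- matrix(0L, 4L, 3L)
    for (s in 1:3) {
      v[s + 1L, ] <- v[s, ]
      v[s + 1L, p[s]] <- 1L
    }
    v
  })
}

#' Isosurface of a binary mask as a triangle mesh
#'
#' Extracts the 0.5-level isosurface of a binary voxel field by marching
#' tetrahedra on the Kuhn (six-tetrahedra) cube subdivision: surface vertices
#' sit at midpoints of grid edges joining an inside and an outside voxel,
#' shared tetrahedron faces match across cubes, and every triangle is wound
#' so its normal points out of the bone region — the result is a watertight,
#' consistently oriented 2-manifold for any mask. The mask is padded by one
#' background layer internally, so objects touching the grid boundary are
#' closed off at the boundary.
#'
#' Vertex coordinates are in mm: voxel `(i, j, k)` (1-based) has its center
#' at `(i-1, j-1, k-1) * spacing`.
#'
#' @param mask 3D binary array.
#' @param spacing Voxel spacing in mm (scalar or length-3).
#' @return A `"triangle_mesh"`; empty (0 triangles) for an empty mask.
#' @export
mask_to_mesh <- function(mask, spacing = 0.2) {
  if (length(dim(mask)) != 3L) stop("'mask' must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("'spacing' must be positive")
  m <- array(0L, dim = dim(mask) + 2L)
  m[2:(dim(mask)[1] + 1), 2:(dim(mask)[2] + 1), 2:(dim(mask)[3] + 1)] <-
    (unclass(mask) != 0) + 0L
  if (sum(m) == 0L)
    return(triangle_mesh(matrix(numeric(0), 0L, 3L),
                         matrix(integer(0), 0L, 3L)))
  d <- dim(m)
  # locate cubes whose 8 corners are not all equal
  cs <- m[-d[1], -d[2], -d[3]] + m[-1, -d[2], -d[3]] +
    m[-d[1], -1, -d[3]] + m[-1, -1, -d[3]] +
    m[-d[1], -d[2], -1] + m[-1, -d[2], -1] +
    m[-d[1], -1, -1] + m[-1, -1, -1]
  mixed <- which(cs > 0L & cs < 8L, arr.ind = TRUE)
  tets <- kuhn_tets()

  tri_coords <- vector("list", 2048L)
  ntri <- 0L
  emit <- function(p1, p2, p3, inside_c, outside_c) {
    nrm <- crossp(p2 - p1, p3 - p1)
    if (sum(nrm * (outside_c - inside_c)) < 0) {
      tmp <- p2
      p2 <- p3
      p3 <- tmp
    }
    ntri <<- ntri + 1L
    if (ntri > length(tri_coords))
      length(tri_coords) <<- 2L * ntri
    tri_coords[[ntri]] <<- rbind(p1, p2, p3)
  }

  for (row in seq_len(nrow(mixed))) {
    base <- as.numeric(mixed[row, ]) # cube origin node (1-based)
    vals8 <- m[base[1] + 0:1, base[2] + 0:1, base[3] + 0:1]
    for (tet in tets) {
      corners <- sweep(tet, 2L, base, `+`) # 4 x 3 node coords
      v <- vals8[cbind(tet[, 1] + 1L, tet[, 2] + 1L, tet[, 3] + 1L)]
      inside <- v == 1L
      ni <- sum(inside)
      if (ni == 0L || ni == 4L) next
      ic <- colMeans(corners[inside, , drop = FALSE])
      oc <- colMeans(corners[!inside, , drop = FALSE])
      if (ni == 1L || ni == 3L) {
        lone <- if (ni == 1L) which(inside) else which(!inside)
        rest <- setdiff(1:4, lone)
        mid <- (corners[rep(lone, 3L), ] + corners[rest, ]) / 2
        emit(mid[1L, ], mid[2L, ], mid[3L, ], ic, oc)
      } else {
        ins <- which(inside)
        outs <- which(!inside)
        m1 <- (corners[ins[1L], ] + corners[outs[1L], ]) / 2
        m2 <- (corners[ins[1L], ] + corners[outs[2L], ]) / 2
        m3 <- (corners[ins[2L], ] + corners[outs[2L], ]) / 2
        m4 <- (corners[ins[2L], ] + corners[outs[1L], ]) / 2
        emit(m1, m2, m3, ic, oc)
        emit(m1, m3, m4, ic, oc)
      }
    }
  }
  tri_coords <- tri_coords[seq_len(ntri)]
  coords <- do.call(rbind, tri_coords) # (3 ntri) x 3, padded-node units
  # weld vertices: doubled coordinates are integers, so keys are exact
  key <- paste(coords[, 1] * 2, coords[, 2] * 2, coords[, 3] * 2)
  idx <- match(key, key[!duplicated(key)])
  verts <- coords[!duplicated(key), , drop = FALSE]
  # padded node (2,2,2) is voxel (1,1,1), i.e. world origin
  verts <- sweep(sweep(verts, 2L, c(2, 2, 2)), 2L, spacing, `*`)
  triangle_mesh(verts, matrix(idx, ncol = 3L, byrow = TRUE))
}

crossp <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Triangulated sphere (subdivided icosahedron)
#'
#' Reference surface for geometric tests: an icosahedron refined
#' `subdivisions` times with vertices projected onto the sphere, wound
#' outward.
#'
#' @param radius Sphere radius (mm).
#' @param center Length-3 center.
#' @param subdivisions Refinement levels (0 = plain icosahedron; each level
#'   quadruples the triangle count).
#' @return A `"triangle_mesh"`.
#' @export
sphere_mesh <- function(radius = 1, center = c(0, 0, 0), subdivisions = 2L) {
  if (radius <= 0) stop("'radius' must be positive")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (lev in seq_len(subdivisions)) {
    edges <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1L,
                            sort)))
    mids <- (v[edges[, 1L], , drop = FALSE] + v[edges[, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    key <- paste(edges[, 1L], edges[, 2L])
    mid_idx <- function(a, b) {
      nrow(v) + match(paste(pmin(a, b), pmax(a, b)), key)
    }
    newf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c_ <- f[i, 3L]
      ab <- mid_idx(a, b); bc <- mid_idx(b, c_); ca <- mid_idx(c_, a)
      newf[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                         c(ab, bc, ca))
    }
    v <- rbind(v, mids)
    f <- do.call(rbind, newf)
  }
  v <- v * radius
  # enforce outward winding (convex: normal must point away from center)
  ctr <- (v[f[, 1L], ] + v[f[, 2L], ] + v[f[, 3L], ]) / 3
  nrm <- face_normals(v, f)
  flip <- rowSums(nrm * ctr) < 0
  f[flip, 2:3] <- f[flip, 3:2]
  v <- sweep(v, 2L, center, `+`)
  triangle_mesh(v, f)
}

#' Signed surface deviations between two meshes
#'
#' Samples the test mesh at its vertices and measures, for each sample, the
#' Euclidean distance to the nearest point on any reference triangle. The
#' sign is taken from the nearest reference triangle's outward normal:
#' positive when the sample lies outside the reference surface. Samples
#' farther than `limit` mm (either sign) are excluded from the statistics
#' and reported through the matched fraction, so nothing is dropped
#' silently.
#'
#' @param test,ref Nonempty `"triangle_mesh"` objects (test = acquired
#'   surface, ref = gold standard).
#' @param limit Search window in mm (default 5).
#' @return Object of class `"deviation_stats"`: `deviations` (matched signed
#'   distances, mm), `matched_fraction`, `n_samples`, `limit`.
#' @seealso [mad_deviation()], [percentile_summary()]
#' @export
signed_deviations <- function(test, ref, limit = 5.0) {
  stopifnot(inherits(test, "triangle_mesh"), inherits(ref, "triangle_mesh"))
  if (nrow(test$triangles) == 0L || nrow(ref$triangles) == 0L)
    stop("both meshes must be nonempty")
  if (limit <= 0) stop("'limit' must be positive")
  d <- cpp_point_mesh_signed(test$vertices, ref$vertices,
                             ref$triangles - 1L, ref$normals)
  matched <- abs(d) <= limit
  structure(list(deviations = d[matched],
                 matched_fraction = mean(matched),
                 n_samples = length(d), limit = limit),
            class = "deviation_stats")
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat(sprintf("surface deviations: %d samples, %.1f%% within +/-%.1f mm\n",
              x$n_samples, 100 * x$matched_fraction, x$limit))
  if (length(x$deviations) > 0L) {
    cat(sprintf("  MAD %.3f mm; median %.3f mm; 10th/90th pct %.3f/%.3f mm\n",
                mad_deviation(x), stats::median(x$deviations),
                quantile(x$deviations, 0.1), quantile(x$deviations, 0.9)))
  } else cat("  no matched samples\n")
  invisible(x)
}

#' Mean absolute surface deviation
#'
#' Mean of `|d|` over the matched signed deviations, in mm.
#'
#' @param stats A `"deviation_stats"` from [signed_deviations()].
#' @return Numeric scalar (mm).
#' @export
mad_deviation <- function(stats) {
  stopifnot(inherits(stats, "deviation_stats"))
  if (length(stats$deviations) == 0L)
    stop("no matched samples within the deviation limit")
  mean(abs(stats$deviations))
}

#' Percentile summary of signed deviations
#'
#' Percentiles of the matched signed deviations by linear interpolation of
#' the sorted values (the 10th/90th pair is the usual whisker range for
#' surface-comparison box plots).
#'
#' @param stats A `"deviation_stats"`.
#' @param probs Probabilities (default 10/25/50/75/90%).
#' @return Named numeric vector (mm), nondecreasing.
#' @export
percentile_summary <- function(stats, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(stats, "deviation_stats"))
  if (length(stats$deviations) == 0L)
    stop("no matched samples within the deviation limit")
  quantile(stats$deviations, probs = probs, type = 7)
}
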