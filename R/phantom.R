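#' Specification of a synthetic dental phantom
#'
#' Describes a desk-scale, jaw-like axial phantom: a soft-tissue ellipse
#' containing a bone arch (mandible-like horseshoe) carrying a row of teeth,
#' optionally a vertebra-like blob on the upper slices, and high-density
#' metal inclusions (fillings) placed inside a random subset of teeth.
#' Geometry varies smoothly with the slice index.
#'
#' Attenuation values are linear coefficients per mm. The defaults (soft
#' tissue 0.02, bone 0.08) are in the range of tissue at CBCT energies. The
#' metal default (3) is a severity calibration rather than a material
#' constant: a desk-scale miniature concentrates each corrupted ray onto far
#' fewer pixels than a clinical-size grid, so a clinical metal coefficient
#' would produce artifacts that obliterate the anatomy. The default is set so
#' that the best achievable global-threshold Dice on corrupted volumes falls
#' in the 0.7-0.8 band that intensity-based methods reach on clinical scans
#' affected by metal artifacts (artifact-free volumes threshold at about
#' 0.95).
#'
#' @param size Slice side length in pixels (square slices).
#' @param n_slices Number of axial slices per volume.
#' @param spacing Isotropic voxel spacing in mm (default 0.2).
#' @param seed Integer seed controlling the metal placement.
#' @param center Arch center in pixels; default slice center.
#' @param arch_radius,arch_thickness,arch_span Arch centerline radius and
#'   radial thickness in pixels, and angular span in degrees.
#' @param n_teeth,tooth_radius Tooth count along the arch and tooth radius
#'   in pixels.
#' @param vertebra If `TRUE`, a vertebra-like bone blob appears on the upper
#'   half of the slices.
#' @param metal_count,metal_radius Number and radius (pixels) of metal
#'   inclusions.
#' @param attenuation Named vector with increasing entries `air <= soft <
#'   bone < metal` (per mm).
#' @param intensity_window Length-2 reconstruction dynamic range (per mm):
#'   reconstructed volumes are clamped to this window, emulating the bounded
#'   output range of clinical scanners (the HU floor/ceiling convention), so
#'   metal saturates at a few times the bone intensity rather than at
#'   arbitrarily large values. Defaults to `c(-0.1, 0.4)`, i.e. 5x the soft
#'   tissue value below zero and 5x bone above.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = 64L, n_slices = 8L, spacing = 0.2, seed = 1L,
                         center = NULL,
                         arch_radius = 0.28 * size,
                         arch_thickness = 0.06 * size,
                         arch_span = 240,
                         n_teeth = 8L, tooth_radius = 0.035 * size,
                         vertebra = TRUE,
                         metal_count = 2L, metal_radius = 0.031 * size,
                         attenuation = c(air = 0, soft = 0.02, bone = 0.08,
                                         metal = 3),
                         intensity_window = c(-0.1, 0.4)) {
  size <- as.integer(size)
  if (size < 16L) stop("'size' must be at least 16 pixels")
  if (spacing <= 0) stop("'spacing' must be positive")
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  att <- attenuation
  if (!all(c("air", "soft", "bone", "metal") %in% names(att)))
    stop("'attenuation' needs entries air, soft, bone, metal")
  if (!(att["metal"] > att["bone"] && att["bone"] > att["soft"] &&
        att["soft"] > att["air"] && att["air"] >= 0))
    stop("attenuation must satisfy metal > bone > soft > air >= 0")
  metal_count <- as.integer(metal_count)
  if (metal_count < 0L || metal_count > n_teeth)
    stop("'metal_count' must be in 0..n_teeth")
  if (length(intensity_window) != 2L ||
      diff(intensity_window) <= 0 || intensity_window[2L] <= att[["bone"]])
    stop("'intensity_window' must be increasing and contain the bone value")
  spec <- structure(
    list(size = size, n_slices = as.integer(n_slices), spacing = spacing,
         seed = as.integer(seed), center = center,
         arch_radius = arch_radius, arch_thickness = arch_thickness,
         arch_span = arch_span, n_teeth = as.integer(n_teeth),
         tooth_radius = tooth_radius, vertebra = isTRUE(vertebra),
         metal_count = metal_count, metal_radius = metal_radius,
         attenuation = att, intensity_window = intensity_window),
    class = "phantom_spec")
  # the arch (plus teeth) must fit inside the soft-tissue ellipse and grid
  reach <- max(spec$arch_radius * 1.1) + spec$arch_thickness / 2 +
    spec$tooth_radius
  if (reach >= 0.48 * size)
    stop("invalid spec: arch geometry does not fit the grid")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("dental phantom: %dx%d px, %d slices, %.2f mm voxels\n",
              x$size, x$size, x$n_slices, x$spacing))
  cat(sprintf("  arch radius %.1f px, %d teeth, %d metal inclusions\n",
              x$arch_radius, x$n_teeth, x$metal_count))
  invisible(x)
}

#' Render one axial phantom slice
#'
#' Produces the piecewise-constant attenuation map of slice `slice_index`
#' together with the exact bone and metal masks. The arch radius scales
#' smoothly with the slice index and a vertebra-like blob appears on the
#' upper half of the stack; metal inclusions sit inside a seed-chosen subset
#' of teeth (the same teeth on every slice of a volume). Masks derive from
#' the geometry, so they are unaffected by any later artifact simulation;
#' metal pixels are excluded from the bone mask.
#'
#' @param spec A [phantom_spec()].
#' @param slice_index 1-based slice index in `1:spec$n_slices`.
#' @param render_metal If `FALSE`, the filling sites are rendered at bone
#'   attenuation (the same patient without the artifact-causing material)
#'   while both masks keep the with-metal geometry — the counterfactual used
#'   to isolate the streaks' effect with identical gold labels.
#' @return `list(image, bone_mask, metal_mask)`: the attenuation map (per
#'   mm) and integer 0/1 masks, all `size x size`.
#' @export
generate_slice_phantom <- function(spec, slice_index, render_metal = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  slice_index <- as.integer(slice_index)
  if (slice_index < 1L || slice_index > spec$n_slices)
    stop("'slice_index' outside the spec's slice range")
  n <- spec$size
  att <- spec$attenuation
  # pixel coordinates: x = column index, y = row index (0-based)
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  cx <- spec$center[1L]
  cy <- spec$center[2L]

  img <- matrix(att[["air"]], n, n)
  soft <- ((x - cx) / (0.45 * n))^2 + ((y - cy) / (0.42 * n))^2 <= 1
  img[soft] <- att[["soft"]]

  frac <- if (spec$n_slices > 1L) (slice_index - 1) / (spec$n_slices - 1) else 0
  Rk <- spec$arch_radius * (0.9 + 0.2 * frac)
  dx <- x - cx
  dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) * 180 / pi # anterior = +90 (larger row index)
  angdist <- abs(((phi - 90 + 180) %% 360) - 180)
  arch <- abs(r - Rk) <= spec$arch_thickness / 2 &
    angdist <= spec$arch_span / 2

  span <- spec$arch_span * 0.85
  tooth_deg <- 90 + seq(-span / 2, span / 2, length.out = spec$n_teeth)
  tooth_cx <- cx + Rk * cos(tooth_deg * pi / 180)
  tooth_cy <- cy + Rk * sin(tooth_deg * pi / 180)
  teeth <- matrix(FALSE, n, n)
  for (t in seq_len(spec$n_teeth))
    teeth <- teeth |
      (x - tooth_cx[t])^2 + (y - tooth_cy[t])^2 <= spec$tooth_radius^2

  metal <- matrix(FALSE, n, n)
  if (spec$metal_count > 0L) {
    chosen <- with_seed(spec$seed,
                        sample.int(spec$n_teeth, spec$metal_count))
    for (t in chosen)
      metal <- metal |
        (x - tooth_cx[t])^2 + (y - tooth_cy[t])^2 <= spec$metal_radius^2
  }

  bone <- arch | teeth
  if (spec$vertebra && frac >= 0.5) {
    vx <- cx
    vy <- cy - 0.32 * n
    bone <- bone | (x - vx)^2 + (y - vy)^2 <= (0.08 * n)^2
  }

  img[bone] <- att[["bone"]]
  img[metal] <- if (render_metal) att[["metal"]] else att[["bone"]]
  bone_mask <- matrix(0L, n, n)
  bone_mask[bone & !metal] <- 1L
  metal_mask <- matrix(0L, n, n)
  metal_mask[metal] <- 1L
  list(image = img, bone_mask = bone_mask, metal_mask = metal_mask)
}

# Per-volume geometry jitter, deterministic in (spec, volume seed).
jitter_spec <- function(spec, seed) {
  with_seed(seed, {
    spec$center <- spec$center + runif(2, -0.02, 0.02) * spec$size
    spec$arch_radius <- spec$arch_radius * runif(1, 0.93, 1.07)
    spec$arch_thickness <- spec$arch_thickness * runif(1, 0.9, 1.1)
    spec$tooth_radius <- spec$tooth_radius * runif(1, 0.9, 1.1)
    spec$seed <- sample.int(2^30, 1) # drives metal placement
  })
  spec
}

#' Generate a labeled synthetic dataset
#'
#' Emulates a set of CBCT-like scans: for each volume, the phantom geometry
#' is independently jittered, every slice is forward-projected
#' ([radon_project()]), corrupted by photon-count noise with beam hardening
#' ([apply_photon_statistics()]) and reconstructed by filtered
#' back-projection ([fbp_reconstruct()]). Gold-standard bone and metal masks
#' come from the pre-artifact geometry, so labels are artifact-free. With at
#' least one metal inclusion the reconstructions show the characteristic
#' bright/dark streaks radiating from the fillings. Reconstructed volumes
#' are clamped to the spec's `intensity_window` (scanner dynamic range).
#'
#' @param spec A [phantom_spec()]; its `metal_count` decides whether streak
#'   sources are present.
#' @param params A [sinogram_params()].
#' @param n_volumes Number of volumes.
#' @param n_slices Slices per volume; defaults to `spec$n_slices`.
#' @param seed Integer master seed (geometry jitter and photon noise).
#' @param corrupt If `FALSE`, skip the photon/noise step and reconstruct the
#'   clean sinogram (used for paired clean/corrupted comparisons; geometry
#'   and masks are identical for equal seeds).
#' @param metal If `FALSE`, render the filling sites at bone attenuation
#'   while keeping the with-metal masks (see [generate_slice_phantom()]):
#'   paired runs with equal seeds then share geometry, labels and the noise
#'   stream, isolating the streaks caused by the metal.
#' @return A list of labeled volumes, each
#'   `list(image, bone_mask, metal_mask, spacing, id)` (class
#'   `"labeled_volume"`) with `image` a `size x size x n_slices` array.
#' @export
generate_dataset <- function(spec, params = sinogram_params(spec),
                             n_volumes = 1L, n_slices = spec$n_slices,
                             seed = 1L, corrupt = TRUE, metal = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 1L) stop("'n_volumes' must be >= 1")
  lapply(seq_len(n_volumes), function(v) {
    vspec <- jitter_spec(spec, seed + 7919L * v)
    vspec$n_slices <- as.integer(n_slices)
    img <- array(0, dim = c(spec$size, spec$size, n_slices))
    bone_m <- array(0L, dim = dim(img))
    metal_m <- array(0L, dim = dim(img))
    for (k in seq_len(n_slices)) {
      ph <- generate_slice_phantom(vspec, k, render_metal = metal)
      sino <- radon_project(ph$image, params, spacing = spec$spacing)
      if (corrupt)
        sino <- with_seed(seed + 7919L * v + 104729L * k,
                          apply_photon_statistics(sino, params))
      rec <- fbp_reconstruct(sino, params, size = spec$size,
                             spacing = spec$spacing)
      # scanner dynamic range: reconstructions are clamped, metal saturates
      img[, , k] <- pmin(pmax(rec, spec$intensity_window[1L]),
                         spec$intensity_window[2L])
      bone_m[, , k] <- ph$bone_mask
      metal_m[, , k] <- ph$metal_mask
    }
    structure(list(image = img, bone_mask = bone_m, metal_mask = metal_m,
                   spacing = rep(spec$spacing, 3L),
                   id = sprintf("vol%02d", v)),
              class = "labeled_volume")
  })
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("labeled volume %s: %d x %d x %d voxels, %.2f mm spacing\n",
              x$id, d[1L], d[2L], d[3L], x$spacing[1L]))
  cat(sprintf("  bone voxels: %d, metal voxels: %d\n",
              sum(x$bone_mask), sum(x$metal_mask)))
  invisible(x)
}
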