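---
title: "Mixed-scale dense networks for bone segmentation under metal artifacts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-scale dense networks for bone segmentation under metal artifacts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdseg)
```

## The problem

Cone-beam CT (CBCT) is the standard volumetric modality in dental and
maxillofacial imaging. Metal objects in the mouth — amalgam fillings, crowns,
implants — attenuate the beam so strongly that the detector receives almost
no photons along some rays ("photon starvation"); together with beam
hardening and scatter this corrupts the reconstruction with bright and dark
streaks radiating from the metal. Intensity-based segmentation methods
(global thresholding, gradient-driven active contours) then fail, because
the streaks introduce intensity values and gradients indistinguishable from
bone edges. `msdseg` implements a mixed-scale dense (MS-D) convolutional
network that learns to separate bone from artifact on 2D axial slices, plus
the complete evaluation chain used to judge such a segmenter: Dice overlap
against gold-standard masks, leave-2-out cross-validation, and geometric
comparison of triangulated surfaces (signed deviations, MAD) through binary
STL files.

## The MS-D network

The network is a stack of `d` hidden layers, each producing a single
feature map of the same height and width as the input slice. Writing
$z_0$ for the (normalized) input slice, layer $i$ computes

$$z_i = \sigma\!\Big(\sum_{j=0}^{i-1} D_{h_{ij},\,s_i} z_j + b_i\Big),$$

where $D_{h,s}$ is a $3\times 3$ convolution whose taps are spaced $s$
pixels apart (a *dilated* convolution), $\sigma$ is the ReLU, and every
previously computed map — the input included — feeds the new layer (*dense
connectivity*). The dilation depends only on the layer index through a
cyclic schedule: $s_i = ((i-1) \bmod 10) + 1$, so scales 1–10 px recur
every ten layers and the network mixes small- and large-scale context
without pooling. All convolutions use reflective boundaries (index $-k$
maps to $+k$; the border pixel is not duplicated; folding repeats so any
dilation remains defined on tiny images), which keeps every feature map
exactly the input's size.

The output layer applies $1\times 1$ weights to all $d+1$ maps and a
two-class softmax:

$$y_c = \mathrm{softmax}_c\Big(\sum_{i=0}^{d} w_{ci} z_i + b_c\Big),
\qquad c \in \{\text{background}, \text{bone}\},$$

and a cutoff on the bone probability yields the binary mask. A probability
exactly equal to the cutoff is labeled bone; the clinical-scale operating
point is 100 layers with cutoff 0.7, tunable per fit.

With width 1, one input channel and two classes the parameter count is
$\sum_{i=1}^{d}(9i + 1) + 2(d+1) + 2 = 9d(d+1)/2 + 3d + 4$; for $d = 100$
this gives `r count_parameters(msd_config(100))` scalars — three orders of
magnitude fewer than encoder–decoder architectures, which is the point of
the design for data-poor clinical training. (Published figures for this
architecture quote 45,756 at depth 100; the enumeration above yields
45,754, a 0.004% difference whose source convention is not documented. We
report the enumerated count and do not force the printed value.)

## Training

`msd_fit()` optimizes the mean per-pixel two-class cross-entropy — the
canonical loss for a softmax output — with Adam at its default settings
(step size $10^{-3}$, moment decays 0.9/0.999, $\epsilon = 10^{-8}$) and
batch size 1: one axial slice per step, in an order reshuffled every epoch
from a seed-derived stream. Hidden kernels are initialized from a zero-mean
normal with standard deviation $1/\sqrt{\text{fan-in}}$ (fan-in $9i$ for
layer $i$; on short training budgets this proved markedly more stable
across seeds than the $\sqrt{2}$-gain variant);
output weights and all biases start at zero, so an untrained network
predicts probability 0.5 everywhere — a useful invariant that the tests
exploit. Inputs are z-scored with the mean and population SD pooled over
the *training* volumes only; the statistics are stored in the fit and
reapplied at prediction time, so held-out data never leak into
normalization.

Everything is deterministic given the seed on a fixed platform:
initialization, shuffling, and the phantom simulator below all draw from
seeded streams and restore the caller's RNG state.

Model selection follows the benchmark protocol: `leave_two_out_folds()`
sorts the scan ids and holds out consecutive pairs (9 folds of 16 train / 2
test for 18 scans; the pairing rule is ours, as the original protocol does
not state how pairs were formed), and `sweep_hyperparameters()` trains one
network per candidate depth and sweeps the cutoff on held-out validation
scans without retraining, breaking ties toward the smaller depth and
cutoff. Epoch counts found on the validation scans are reused unchanged in
the cross-validation runs.

## The synthetic phantom

Clinical CBCT scans with expert gold standards are not redistributable, so
the package ships a seeded generator whose volumes stand in for them. Each
axial slice contains a soft-tissue ellipse, a mandible-like bone arch
carrying a row of teeth (geometry drifting smoothly with the slice index,
plus a vertebra-like blob on upper slices), and metal "fillings" inside a
seeded subset of teeth. Per-volume jitter perturbs center, radii and
thickness so volumes are distinct but statistically alike. Gold-standard
bone and metal masks come from this pre-artifact geometry and are therefore
artifact-free by construction, like expert segmentations.

The artifact chain is physics-motivated but deliberately minimal:

1. **Forward projection** — parallel-beam line integrals (90 angles over
   180°, detector pitch = pixel pitch, 4 sub-rays per bin, quarter-pixel
   sampling). Parallel rather than cone-beam geometry: it reproduces the
   streak phenomenology at a fraction of the complexity, and the artifact
   mechanism is in-plane.
2. **Photon statistics** — beam hardening shrinks each line integral $p$
   to $p' = p - \alpha p^2$ ($\alpha = 0.01$; the simplest monotone
   correction that produces dark bands between metal objects), the
   detector draws $\mathrm{Poisson}(I_0 e^{-p'})$ counts with
   $I_0 = 10^5$, counts clamp at one photon (photon starvation: rays
   through metal saturate at $\ln I_0$ and their information is lost), and
   the corrupted integral is $-\ln(\text{counts}/I_0)$.
3. **Filtered back-projection** — discrete band-limited ramp filter
   (spatial-domain kernel, FFT convolution) and bilinear back-projection,
   reconstructing attenuation per mm on the original grid.
4. **Dynamic range** — the reconstruction is clamped to an intensity
   window (default $[-0.1, 0.4]$ per mm, i.e. five times the soft-tissue
   value below zero and five times bone above). Clinical scanners bound
   their output the same way (the $-1000$/$+3000$ HU convention): metal
   saturates at a few times the bone intensity instead of the arbitrarily
   large values raw filtered back-projection produces. Without this stage,
   z-scored metal pixels become $\sim 30\sigma$ outliers that dominate the
   early training gradients through the dense connections.

Attenuation defaults are 0 (air), 0.02 (soft tissue) and 0.08 /mm (bone),
in the range of tissue values at CBCT energies, with 0.2 mm isotropic
voxels. The metal coefficient (3 /mm) is a *severity calibration*, not a
material constant: a 64-pixel miniature concentrates each corrupted ray
onto roughly an eighth of the pixels a clinical-size grid would spread it
over, so rendering metal at a clinical coefficient obliterates the anatomy
entirely. The default is chosen so that the best achievable global
threshold reaches a Dice of roughly 0.7–0.8 on corrupted volumes — the
performance band that intensity-based clinical methods occupy on
artifact-affected scans — while artifact-free volumes threshold at about
0.95. A `metal = FALSE` rendering mode re-renders the filling sites at
bone attenuation with *unchanged* geometry and masks, giving paired
volumes that isolate the streaks' causal effect under identical labels and
noise streams.

What the phantom does *not* emulate: scanner-accurate spectra and scatter
kernels, detector response, anatomical realism beyond jaw-arch topology,
and 3D (cone-beam) artifact structure. Passing tests therefore demonstrate
that the implementation learns to reject streak-like corruption that
defeats thresholding — not clinical-grade performance on real scans.

## Evaluation chain

Voxel overlap uses the Dice similarity coefficient
$\mathrm{DSC} = 2\,\mathrm{TP} / (2\,\mathrm{TP} + \mathrm{FP} +
\mathrm{FN})$ with bone as the positive class. When both masks are empty
the coefficient is undefined and the package raises an error rather than
adopting a silent convention. Summary tables report mean ± SD per method;
the population SD is used (with 18 scans both conventions agree at the
two-decimal presentation precision, so the choice is presentational), and
display rounding is half-up at two decimals. The package ships the
per-patient Dice table of the published 18-scan benchmark
(`dice_reference_table()`) and reproduces its printed summary row exactly.

The geometric chain converts masks to surfaces with marching tetrahedra on
the Kuhn (six-tetrahedra) cube subdivision at the 0.5 level of the binary
field. We chose marching tetrahedra over table-driven marching cubes
because it has no ambiguous configurations — every binary mask yields a
watertight, consistently outward-oriented 2-manifold — and the per-tet
case analysis (one or two triangles, orientation fixed by the
inside/outside centroids) is small enough to verify by hand. Vertices sit
at grid-edge midpoints in mm coordinates (voxel $(i,j,k)$, 1-based, has
its center at $(i\!-\!1, j\!-\!1, k\!-\!1)\times$spacing); the mask is
padded by one background layer so boundary-touching objects close. The
cost is more, smaller triangles than marching cubes would produce.

Surfaces are exchanged as binary STL (80-byte header, little-endian
`uint32` count, 50 bytes per triangle), the dialect 3D-printing toolchains
consume; round trips are bit-exact at 32-bit float precision.

`signed_deviations()` samples the *test* mesh at its vertices and measures
the true point-to-triangle distance to the *reference* (gold) mesh, signed
by the nearest reference triangle's outward normal (positive = outside the
gold surface). Vertex sampling was chosen over area-weighted random
sampling for determinism; sampling direction and density are known sources
of deviation versus commercial surface-comparison tools, whose conventions
are not published — absolute MAD values from such tools are therefore not
bit-reproducible even in principle. Samples beyond ±5 mm are excluded from
the statistics, not clamped, and the matched fraction is always reported
so nothing is dropped silently. MAD is the mean absolute matched
deviation; percentiles (10/25/50/75/90) use linear interpolation of the
sorted values.

## Numerical choices and degenerate inputs

* Reflection convention: mirror about the border pixel without duplicating
  it, folded repeatedly — keeps dilations larger than the image legal.
* Binarization ties (probability = cutoff) label bone, making the mask
  count monotone nonincreasing in the cutoff.
* Cross-entropy logs are stabilized with a $10^{-12}$ floor; softmax
  subtracts the per-pixel max logit.
* Poisson draws with expected counts above $10^9$ switch to the Gaussian
  limit (the sampler's validity region ends there; at $I_0 = 10^5$ this
  only affects noise-free extremes).
* Constant training volumes make the z-score undefined: an error, not a
  fallback.
* Empty masks mesh to an empty (flagged) mesh; deviation statistics on
  empty meshes raise.

## Problem sizes

The shipped tests and the acceptance script run entirely at desk scale,
chosen as the smallest sizes at which every mechanism is exercised
meaningfully: 64×64 slices, depth-20 networks, 480 batch-size-1 steps for
the end-to-end recovery experiment (about a minute on one CPU core; five
training volumes, one validation volume on which the cutoff is selected,
one held-out volume), and 32–48 px phantoms for the mechanism tests. The clinical-scale configuration
(depth 100, cutoff 0.7, 10 epochs) is a constructor default and trains the
same way, only longer.

## Known limitations

* 2D slice-wise segmentation only; no 3D convolutions.
* The phantom's streak statistics are parallel-beam and in-plane; real
  cone-beam artifacts have out-of-plane structure.
* No data augmentation, learning-rate schedules or early stopping — the
  training protocol is deliberately the plain batch-size-1 Adam recipe.
* Mesh extraction is unsmoothed; staircase effects dominate sub-voxel
  accuracy, which is why surface tests compare against analytic spheres.
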