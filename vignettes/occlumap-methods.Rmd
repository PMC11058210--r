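---
title: "Depth-map projection and generative reconstruction of occlusal surfaces"
author: "occlumap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-map projection and generative reconstruction of occlusal surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A dental inlay must restore the chewing (occlusal) surface of a prepared
molar so that the restoration meets the preparation edge exactly and the
restored relief is anatomically plausible. `occlumap` treats this as a
constrained image-inpainting problem: the prepared tooth is projected
into a calibrated 8-bit depth map, the preparation area is extracted as a
binary mask, and the missing region is filled by inverting a generative
model of healthy occlusal surfaces under a loss that pins the fill to the
preparation edge. The merged depth map is finally back-projected to a
heightfield mesh.

The package contains every stage as a testable unit — pose
normalization, projection, mask extraction, generator fitting, latent
inversion, merging, back-projection, and a millimetre-scale evaluation
protocol — together with a parametric synthetic-molar generator that
provides ground truth for all of them.

# Pose normalization

Scanned crowns arrive in arbitrary scanner coordinate frames. Two
rotations normalize the pose:

1. **Bounding-box derotation.** The minimum-volume oriented bounding box
   of the mesh is found by enumerating candidate face orientations from
   triples of a directional-extreme-point subset of the cloud (plus the
   PCA frame and the identity), closing each candidate with a
   rotating-calipers rectangle in the face plane. Extents are always
   measured over the full cloud, so the returned box contains every
   point, and the identity candidate guarantees the volume never exceeds
   the axis-aligned box. The box is defined only up to its 24-element
   symmetry group; axes are ordered by extent and the up-direction is
   resolved by a bumpiness heuristic: of the two z-sign choices, the one
   whose high-normal-z point subset shows the larger residual height
   spread is the cusp-bearing occlusal side (the basal side of a closed
   crown is flat). The cheek-facing (buccal) side cannot be inferred
   from geometry at all; synthetic teeth carry an explicit annotation,
   and real scans need one — without it a 180 degree in-plane ambiguity
   remains.

2. **Occlusal-plane leveling.** Points whose unit normals exceed a
   threshold in z (default 0.9) — cusp tops and fossa bottoms — are fit
   with a PCA plane (identical to the total-least-squares SVD plane); the
   rotation built from the plane's two slopes levels it while leaving the
   rotation about z untouched. Because the thresholded subset shifts
   slightly with the pose, the leveling is iterated to convergence
   (tolerance 1e-5 rad, at most 12 iterations); a single pass leaves a
   residual tilt of order one degree.

The slope-based rotation of the leveling step is not exactly orthonormal
when both slopes are nonzero; the package keeps the x-image and the exact
plane normal and re-orthogonalizes the y-image (a correction of order
slope-x times slope-y), so the applied map is a true rotation.

Finally the residual rotation about z is fixed by the minimum-area
bounding rectangle of the leveled silhouette, with the buccal annotation
selecting among the four quadrant choices. This makes
`normalizeOrientation()` idempotent to machine precision and the whole
pipeline invariant to rigid transforms of the input.

# Projection

The normalized mesh is sampled uniformly by area (default 1e5 points;
the full-scale configuration uses 3.3e6 at 256 x 256 — the package's
default of 128 x 128 keeps the per-pixel density comparable), shifted so
the highest point sits at the top of the depth window, and rasterized:
each pixel keeps the maximum sampled height in its footprint, scaled
linearly to intensity 255 at the window top; pixels with no sample or
only sub-window geometry are exactly 0. Intensities stay continuous
inside the pipeline and are quantized once on export.

Two parameters matter:

* `planeSize` (16 mm default) — side of the projection plane; must cover
  the dataset's largest crown plus a margin so no contour touches the
  border.
* `zNorm` (4.5 mm default) — the depth window. The window is sized to
  the occlusal relief of the population (cusp tip to preparation floor,
  with margin). A window just large enough maximizes depth resolution
  (one intensity unit is zNorm/255 mm, about 18 µm at the default) and
  cuts away the crown base and side walls, so the silhouette fades
  toward zero at the cervical fall-off exactly as in scanned-crown depth
  maps. An oversized window would place a multi-millimetre intensity
  cliff at the contour, whose half-covered pixels flicker with the
  sampling seed and dominate the repeatability error.

Two desk-scale rasterization artifacts are corrected explicitly, both
absent at full-scale sampling density: isolated foreground pixels that
received no top-surface sample (filled from their neighbourhood when at
least 7 of 8 neighbours sit more than 50 intensity units higher — no
anatomical or preparation feature drops that steeply relative to its
entire neighbourhood, so true edges are never touched), and the mask
pass is drawn at 8x density because presence-based binarization flags
every empty pixel as removed.

Repeatability is quantified as the 95 percent confidence interval of the
mm RMSE between repeated projections of the same mesh under different
sampling seeds; at the package defaults the interval sits near
0.025 mm, well below the 0.05 mm bound asserted in the tests. For a
fixed seed the projection is bit-reproducible, and because area-weighted
sampling is invariant under rigid transforms, projecting the same tooth
from two poses with one seed yields identical maps up to normalization
error.

# Preparation-mask extraction

Cavity walls are far steeper than any occlusal feature and the cavity
floor sits low; points failing either test (normal z below `nzT`, height
below `zT`) are removed and the survivors are projected and binarized:
white where retained surface exists, black elsewhere. Triangle (face)
normals are used here — they stay sharp at the preparation edge, whereas
the interpolated vertex normals used for plane fitting smear across it.
Both thresholds are empirical per preparation; for the synthetic
fixtures `nzT = 0.3` separates the steepest cusp flanks (normal z about
0.35) from the near-vertical walls (about 0.03), and `zT` is set
0.2 mm above the cavity floor — which also defines the method's
detection floor: removals shallower than 0.2 mm are invisible to the
heuristic by construction.

The finalization step automates the gap-filling that raw projected masks
need: background outside the silhouette is whitened, thin black arcs
hugging the outer contour (grazing-tangent sampling artifacts, never
deeper than 2 px into the tooth) are dropped, isolated speckles below
10 px are removed, a 3 x 3 closing of the black region fills the
single-pixel white notches that partial occlusal slivers leave along the
edge, and enclosed white holes below 10 px are filled. None of these
steps can move a preparation boundary by more than one pixel, and the
operation is idempotent. A user-supplied override mask is honored
verbatim.

Edge coincidence is verified against the analytic carve geometry of the
synthetic teeth. The continuous preparation edge admits two pixel
discretizations — pixels entirely removed (and deeper than the detection
floor) versus pixels touched by removal — and the tests require the
extracted boundary to lie within one pixel of that bracket band in both
directions, excluding the section where an open preparation's boundary
follows the tooth silhouette itself. All four preparation types satisfy
this with zero violations at the package defaults.

# The generator and its desk-scale stand-in

The reconstruction operates on a fixed generator G(w) mapping an
nRes x 512 latent matrix (nRes = 2(log2(width) - 1), i.e. 12 at 128,
14 at 256) to an occlusal depth map. The full-scale model is a
style-based GAN trained offline (its training configuration — Adam with
step 0.002, betas 0/0.99, minibatch 32, path-length regularization 10
with decay 0.99, 7e5 images shown, an 89/3 split mirrored to 178
training images — is recorded verbatim in `styleganTrainingConfig()` and
adapters must not silently change it). The package does not retrain it;
any conforming generator plugs in through the `ToothGenerator` contract
(deterministic evaluation, analytic adjoint, latent mean).

The in-package stand-in is a linear PCA generator:
`clip(mean + B fold(w), 0, 255)`, where `fold` averages the latent rows
and keeps the first `rank` entries, and the columns of B are principal
components of the training maps scaled by their singular values so
latent coefficients are O(1) — mirroring the unit-scale latent
convention of style-based generators and letting Adam's 0.05 step size
converge in a few hundred iterations. Sharing one folded vector across
rows keeps the row-colinearity loss meaningful: rows can disagree during
optimization exactly as per-resolution style inputs can.

# The reconstruction objective

The corrupted input is the Hadamard product of the preparation map with
the binary mask. The objective combines five terms, each normalized per
entry so the published weights are scale-comparable: a masked pixel term
(weight 6.7e-4), a masked perceptual term (9.2e3), a latent prior
(-3.2), a latent row-colinearity term (8.6e-4), and the boundary term
(4.0e-4) — a squared error evaluated only on the one-pixel ring of
retained pixels surrounding the removed region, which forces the
generated fill to meet the preparation edge smoothly.

Two deliberate choices:

* The negative prior weight is honored exactly as published. It rewards
  distance from the latent mean; in latent directions the generator
  ignores, the objective is therefore unbounded below, but Adam's
  bounded per-step displacement keeps every finite-length run finite and
  the reconstruction itself (which only sees the folded rank) is
  unaffected. A flag flips the sign for experimentation.
* The perceptual extractor is a fixed-seed bank of random multi-scale
  convolution kernels applied circularly in the Fourier domain with
  average pooling. It is linear, so its adjoint is exact and the whole
  objective has an analytic gradient (verified against central finite
  differences term by term, relative error below 1e-4). A pretrained
  perceptual network can be substituted through the same two-function
  interface.

Optimization runs Adam (step 0.05, betas 0.9/0.999) for up to 2000
steps per restart, with several restarts initialized from unit Gaussian
draws around the latent mean; the restart with the minimal final loss is
kept. With only the pixel term active the objective is convex in the
folded latent and the optimizer reproduces the masked normal-equations
solution to a relative gap below 1e-3 — the tests verify this for
interior masks up to half the tooth area. The point of diminishing
returns of a loss trace is defined as the first step at which the
relative decrease over a trailing 50-step window falls below 1e-3 (both
constants configurable; the definition is the package's own).

Merging is exact by construction: retained pixels keep the corrupted
input bit-for-bit, removed pixels take the generated fill, so the
boundary condition on the preparation edge holds identically.

# Synthetic molars

The generator of study material builds crowns as a superellipse-footprint
dome (default 11 x 10 mm, about 7.3 mm tall) with four Gaussian cusps, a
central Gaussian fossa, and band-limited surface noise (0.05 mm rms),
closed by vertical side walls and a flat base — a watertight mesh whose
top surface is an analytic heightfield, so projection and mask tests
have exact oracles. Populations jitter the footprint radii (±8
percent), cusp positions (0.25 mm), cusp heights and fossa depth (±15
percent), with an independent noise field per tooth. Four preparation
types of rising removed area (about 0.29/0.44/0.60/0.75 of the visible
occlusal area; type "a" interior, "b"–"d" opening the outer contour)
are carved with near-vertical walls (1.5 degrees from vertical), floors
at 3.0–3.3 mm, and cavity footprints sized numerically against the
visible occlusal region so the fractions hold for any crown dimensions.

What the synthetic data do not emulate: real enamel texture and
scanner noise spectra, anatomical cusp/ridge topology beyond four cusps
and one fossa, undercuts (the top surface is single-valued by
construction), multi-tooth scenes, and a clinically trained generative
prior. Passing tests therefore demonstrate the correctness and internal
consistency of the pipeline's geometry, masking, optimization and
evaluation machinery — not clinical reconstruction quality, which
depends on a full-scale generator trained on real crowns.

# Problem sizes and numerical choices

The packaged experiments run at 128 x 128 with 1e5 samples per
projection, populations of about 45 teeth, a rank-16 linear generator,
and 200–2000 Adam steps with 1–2 restarts; these sizes are the package's
own desk-scale study conditions and run in minutes on one CPU. Other
fixed choices: quantization is round-half-away-from-zero applied once on
export; the empty-subset, vertical-plane, degenerate-footprint,
infeasible-mask-fraction and non-power-of-two-resolution cases all fail
fast with diagnostics; ties in the maximum-z rasterization resolve to
the last-sorted sample (deterministic for a fixed seed); the boundary
ring uses 8-connectivity dilation of width 1.

On this synthetic testbed the full method reproduces the qualitative
findings the evaluation module is built to measure: mean reconstruction
error rises monotonically with the relative circle-mask area over
0.1–0.7 (Spearman rho = 1 in the packaged runs, with a strong linear
trend of the per-fraction means), and at an equal 30 percent removed
area an interior mask reconstructs about twice as well as a mask cutting
the outer contour, because the contour carries exactly the geometric
information the generator must otherwise guess.

# Known limitations

* The buccal side must be annotated; geometry alone leaves a 180 degree
  ambiguity.
* The mask heuristic needs preparations at least 0.2 mm deep and walls
  markedly steeper than the occlusal relief; shallow feather-edge
  preparations are below its detection floor.
* The linear generator can only interpolate the training population's
  principal components; it is a contract-complete stand-in for
  optimization research, not an anatomical prior.
* Error distances are vertical (per-pixel depth) differences; true 3D
  point-to-surface distances can be obtained by back-projecting both
  maps but are not the default.
* At desk-scale sampling density, a handful of half-covered contour
  pixels remain seed-sensitive; they are the dominant term in the
  projection repeatability budget.
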