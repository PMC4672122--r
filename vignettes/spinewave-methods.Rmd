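---
title: "Dendritic spine detection with wavelet symmetry analysis and a morphological shared-weight network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic spine detection with wavelet symmetry analysis and a morphological shared-weight network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`spinewave` detects dendritic spines — the micron-scale protrusions on a
neuron's dendrites where most excitatory synapses form — in 2D
fluorescence micrographs, and classifies each spine into the three
canonical morphologies: *mushroom* (bulbous head on a thin neck),
*stubby* (head directly on the dendrite, no neck) and *thin* (long
narrow neck, little or no head). Changes in the distribution of these
classes accompany several neurological disorders, which makes automated
spine counting and typing a routine need in neurobiology labs.

The pipeline has four stages:

1. **Preprocessing** — 2D median filtering against photomultiplier
   noise, followed by edge-preserving (Perona–Malik) diffusion; local
   Otsu binarization and isolated point-set removal give a foreground
   mask.
2. **Backbone extraction** — wavelet modulus-maxima contour detection
   and *conditional symmetric pairing*: opposite contour points whose
   separation matches the wavelet scale are paired, and their midpoints
   trace the one-pixel-wide dendrite centerline.
3. **Boundary localization** — from each backbone point the image is
   searched perpendicular to the local line direction until the
   intensity drops below a threshold α; gaps between boundary points
   are closed with discrete (midpoint-algorithm) lines.
4. **Spine detection and classification** — a regularized morphological
   shared-weight neural network (RMSNN) scans the image to produce
   per-class detection planes; foreground components outside the
   reconstructed dendrite trunk become spine candidates, each
   characterized geometrically (area, perimeter, maximum width,
   geodesic length, center) and classified by the RMSNN.

Because the original image base is not distributable, the package
includes a first-class synthetic generator that renders confocal-like
dendrite scenes and labeled 20×20 spine subimage libraries with full
ground truth; all quantitative claims in the test suite are made on
those synthetic conditions.

# The RMSNN

The feature-extraction phase is a stack of **gray-scale Hit–Miss
layers**. Each feature map owns a pair of structuring elements (SEs) on
a disk domain — one *hit* SE probing how the image fits above the
template from below, one *miss* SE probing the fit from above:

$$\mathrm{net}^h_y = \min_{x \in D}\,\big(a(x) - t^h_y(x)\big),\qquad
  \mathrm{net}^m_y = \max_{x \in D}\,\big(a(x) - t^m_y(x)\big),\qquad
  a_y = \mathrm{net}^h_y - \mathrm{net}^m_y .$$

The same SE pair is shared across all window positions (hence
*shared-weight*), each layer keeps the input size by replicate padding
at stride 1, and the difference of the two extrema cancels any additive
intensity offset — the features, and therefore the whole network
output, are exactly invariant to gray-level shifts, which is the
property that makes the operator attractive for fluorescence data with
variable expression levels.

The classification phase is a fully connected sigmoid network (ten
hidden units, three output nodes, one per class) reading the flattened
last feature layer. Training is plain per-sample gradient descent on
the squared error $E = \tfrac12\sum_o (t_o - O_o)^2$ with one-hot
targets. Gradients flow through the min/max nodes by subgradient: only
the arg-extremal SE element of each window receives an update, with
ties broken deterministically at the first raster-order element; shared
SEs accumulate their updates over all window positions before they are
applied.

**Weight elimination.** The regularized cost is
$R = E_s + \lambda E_c$ with
$E_c = \sum_w \frac{(w/w_0)^2}{1 + (w/w_0)^2}$ — near-quadratic for
$|w| \ll w_0$ (driving small weights to zero) and saturating at 1 for
large weights. The penalty gradient is applied to the classifier
connection weights at every sample step; `regularize_ses = TRUE`
extends it to the SE values. The reference protocol fixes the
learning rate (0.0015), the SE domain (disk, radius 4 px), the hidden
layer (10 units) and the classifier initialization (uniform
$[-1, 1]$); λ and $w_0$ are not stated and default to $10^{-4}$ and 1.

**Choices the reference protocol leaves open, and what this package does:**

* *Feature maps per layer* — 2 maps in each of 2 layers, the smallest
  shared-weight configuration that exercises the multi-layer delta
  rule; map $j$ of a layer reads map $j$ of the previous layer.
* *SE initialization* — uniform $[-0.1, 0.1]$. The stated $[-1,1]$
  range is read as the classifier weights; near-zero SEs start every
  Hit–Miss node close to the local-contrast operator that flat SEs
  compute, and the small asymmetry breaks the symmetry between maps.
* *Stopping* — mean per-sample error against `mse_target` (default
  $10^{-3}$), a hard epoch cap, and an optional plateau stop
  (`patience`). The cross-validation protocol trains each fold to the
  preset error level 0.014 — just below the plateau of converged runs
  on this problem — capped at 1000 epochs. The cap matters: roughly
  one initialization in ten starts in a poor basin and needs most of
  it, converging to the same error and accuracy as the others, merely
  later.
* *Median-squared error* — reported per epoch as a monitoring
  statistic; the trained loss is the summed squared error above.

# Backbone by conditional symmetry

At scale $s$ the wavelet gradient is
$W_{x,s}f = s\,\partial_x (f * \theta_s)$,
$W_{y,s}f = s\,\partial_y (f * \theta_s)$ with
$\theta_s(x,y) = s^{-2}\theta(x/s, y/s)$ a unit-mass low-pass kernel
(by default an isotropic Gaussian with σ = `sigma0`·s, `sigma0 = 0.35`;
a best-effort reading of the piecewise rational-log basis is available
as `kernel = "piecewise_phi"`, but its printed form is typographically
ambiguous, so the Gaussian family is the default).
Contour points are modulus maxima along the gradient direction. The
suppression uses a strict comparison on the uphill side with a relative
ε ≈ 10⁻⁹ so that the two-pixel tie of a symmetric discrete edge
resolves to the interior pixel.

Two contour points form a **conditional symmetric pair** when marching
from one along its gradient direction (into the bright stroke) reaches
the other, their gradients are opposite within π/4, their separation
matches the scale within `max(1, 0.2 s)`, the midpoint lies in the
foreground mask, *and* the separation matches the width of the regular
region — measured as the foreground run length through the midpoint
along the pairing direction. Pairs failing any test are *unstable
symmetry* and are discarded. The default scale sweep {3, 5, 7, 9, 11,
13} px brackets typical dendrite widths at 0.24 µm/px; at each midpoint
pixel the pair whose separation best matches its scale wins.

Midpoints are rasterized, closed (dilation 5×5 / erosion 3×3 — a
pinhole would survive thinning as a loop and fragment the centerline),
thinned (Zhang–Suen), split at branch points (crossing number ≥ 3; a
plain neighbour count misreads 8-connected staircase corners), and
pruned: dead-end branches shorter than `spur_length = 22` px — chosen
just above the 20 px spine envelope so that the centreline stubs large
spines grow are removed — and isolated skeletons shorter than
`min_path_length = 20` px (a detached spine's own skeleton, not a
dendrite). A second pass then re-extracts the backbone without pairs
much wider than the local regular width estimated from the first pass:
such pairs read across dendrite *plus* attached spine and drag the
centerline into the protrusion. Path ends are truncated at sharp
(> 75°) turns within a spine envelope of the end, then extended along
the stroke to recover the rounded tube end caps (which produce no
symmetric pairs), and every point is re-centred on the midpoint of the
local mask chord perpendicular to the path — rounded pair midpoints
otherwise carry a systematic one-pixel lateral bias on diagonal
stretches. Two re-centring passes are used; the second works with the
tangents of the already-corrected chain.

Per-point width is the pair separation projected on the pairing
direction (the Euclidean separation of a diagonal pair overstates the
stroke width), and the tangent is the local chord direction.

# Boundary and trunk

Eq-(9)-style membership — a pixel belongs to the line while
$I(p) \ge \alpha$ — is used twice:

* **Boundary search** (`alpha_mode = "fraction_of_backbone"`, fraction
  0.5): α is half the intensity at the backbone point, which adapts to
  intensity variation along the dendrite; a global-α mode is also
  provided since both readings of the threshold are defensible.
* **Spine segmentation** uses a lower fraction (`seg_alpha_frac` =
  0.35 of the median backbone intensity) evaluated on the
  diffusion-enhanced image *without* median filtering: thin spine necks
  are narrower than the optical resolution, so they render dimmer than
  the trunk (partial-volume effect) and a 3×3 median erases them
  entirely.

The dendrite **trunk** between the two boundary chains is realized as
the union of the backbone's inscribed disks: at every backbone point
the radius is the distance to the nearest background pixel, smoothed by
a running median over a window wider than a spine footprint. A
one-sided protrusion barely moves the inscribed radius, whereas any
width read *across* the protrusion would absorb the whole spine into
the trunk — stubby spines, which sit directly on the dendrite, are the
reason for this construction. The backbone is extrapolated along its
end tangents so the rounded tube ends (which produce no symmetric
pairs) are still claimed.

Foreground components outside the trunk become spine candidates
(`min_area` = 4 px; components split by a one-pixel threshold dropout
are rejoined by labeling a one-pixel dilation), flagged *attached* when
contiguous with the trunk and *detached* within `detach_dist` = 5 px.
Each is characterized (area; contour-pixel perimeter; maximal extent
perpendicular to the principal axis; geodesic length from the
attachment point with diagonal steps √2; centroid) and classified by
the RMSNN from a masked patch — the component (dilated by one pixel)
against a flat background, the same presentation as the `"masked"`
library below. The detection planes produced by scanning the image
(stride 2, non-maximum suppression within one window size, candidates
require an intensity range ≥ 0.1 inside the window since a
structureless window carries no shape information for shift-invariant
features) are reported alongside and matched to the nearest component.

# The synthetic generator

`make_dendrite_image()` renders a smooth spline dendrite with a
per-point width profile (4–12 px), stamps spines of the three classes
at arc-length positions, applies a Gaussian PSF surrogate (σ = 0.7 px)
and Poisson shot noise (400 photons at full scale) plus additive
Gaussian read-out noise (σ = 0.02) as the photomultiplier surrogate,
and reports full ground truth. Geometry ranges (px) were chosen once to
satisfy the qualitative class descriptions and the 20×20 envelope
(thin ≈ 5×20): mushroom neck 4–7 long and 1.6–2.4 wide with head
radius 3–4.5; stubby head radius 2.5–3.8 and no neck; thin neck 10–15
long and 1.0–1.8 wide with head no larger than the neck width. At
0.24 µm/px these correspond to heads of ~0.6–1.1 µm radius and necks of
~0.25–0.6 µm — no physical spine dimensions are prescribed, so these are free
parameters fixed at biologically plausible values.

`make_spine_library()` draws labeled 20×20 subimages with randomized
orientation, geometry, intensity and blur. Three presentations exist
because a "spine subimage" is genuinely ambiguous: `"isolated"`
(default) renders the bare spine — a clean golden-standard exemplar,
used for the cross-validated accuracy protocol; `"masked"` renders a
dendrite tile carrying the spine, degrades it, and cuts out the
protrusion beyond the (slightly widened) dendrite boundary — exactly
what an expert marks, and exactly the presentation the pipeline
reproduces for segmented candidates, so the deployment model for
whole-scene detection is trained on it; `"tile"` keeps the dendrite in
frame. Classifying raw tiles is markedly harder for this small network,
which is one reason the masked protrusion presentation is used
end-to-end.

**What the generator does not emulate:** realistic PSF anisotropy and
depth attenuation, autofluorescence background structure, crossing or
branching dendrites, axons and other processes in frame, spine motility
or 3D pose foreshortening. Passing tests therefore demonstrate the
method's behaviour under idealized-but-noisy conditions, not
performance on real micrographs.

# Numerical choices and degenerate inputs

* Local Otsu maximizes between-class variance exactly over the
  observed values per tile (ties → lowest threshold); constant tiles
  and tiles whose two classes differ by less than `min_contrast` = 0.1
  in mean (background-only tiles, which Otsu would otherwise split in
  half) map to background.
* Perona–Malik uses the explicit 4-neighbour scheme with exponential
  conductance; `dt` must be ≤ 0.25 (stability), so the scheme obeys a
  maximum principle and never expands the intensity range.
* All morphology uses replicate padding except set-definition binary
  morphology, where off-frame pixels are background (and belong to the
  complement when eroding it).
* min/max subgradients go to the first raster-order arg-extremum;
  training is bit-deterministic given the seed (a Mersenne Twister
  drives the per-epoch presentation order).
* Divergent training (non-finite error) aborts with a diagnostic
  rather than returning a broken model.

# Known limitations

* A spine lying tangentially at a sharp dendrite bend can be traversed
  by the backbone and then fragments into several records; the
  sharp-turn truncation catches only part of these configurations.
* Stubby spines attached to wide dendrite sections keep only a thin
  crescent outside the trunk; very small stubbies can drop below
  `min_area` after trunk subtraction.
* Short-neck mushrooms and large stubbies are intrinsically adjacent
  classes; most residual classification errors are mushroom↔stubby,
  the same confusion structure the underlying method reports.
* The problem sizes used by the test suite and the acceptance script —
  300 subimages per class, 300 training epochs per fold, 640 px scenes
  at stride 2 — were chosen so a complete run stays in the minutes
  range on one CPU while leaving the error curves flat at stop time.
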