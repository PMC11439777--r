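---
title: "Synthetic training data for greenhouse disease detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic training data for greenhouse disease detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytosynth)
```

phytosynth implements an end-to-end pipeline for developing an image
classifier of healthy versus infected tomato branches trained *exclusively*
on procedurally generated images. This vignette documents the models behind
each stage, the tunable parameters and their defaults, the design decisions
taken where the problem was genuinely open, and what the shipped tests do
and do not establish.

## The formal setting

Images live in a space $I$; a generator $G: I \to L$ assigns each image its
true label from $L = \{\text{healthy}, \text{infected}\}$. A dataset
$D = \{(i, G(i))\}$ of synthetic images is produced by a parametric
procedural model plus a random seed, so $G$ is known by construction and
labeling costs nothing. A network $N_w$ is fit by a training function
$T(h, D) = N_w$, $w = \arg\min_{w'} \sum_{i \in D} \lVert N_{w'}(i), G(i)\rVert$
with categorical cross-entropy as the label dissimilarity $\lVert\cdot\rVert$
and $h$ the hyperparameter vector (resolution, batch size, learning rate,
augmentation regime and schedule). Development proceeds in iterations
$\mathcal{I}_k$ that refine the generator and $h$; each iteration has cost
$C_k = C^E_k + C^M_k + C^R_k + C^T_k$ (evaluation, modeling, rendering,
training; the first two are human hours, the last two compute hours), and
development stops as soon as the achieved quality $q$ reaches the target
$q_{\min}$ (default 0.9). The `devloop` functions are the bookkeeping for
exactly this model: `iteration_cost()`, `total_cost()`,
`human_compute_split()`, `stop_rule_met()`.

## Plant geometry

A branch is a circular arc of prescribed arc length and curvature, sampled
as a 33-point polyline (chord-length error is far below the 1% contract).
Leaves are placed at jittered internode positions and rotated around the
local tangent by a phyllotaxis angle (default near the botanical 137.5°).
The radial direction is flattened toward the viewing plane and each blade's
up-vector is jittered around the camera axis: canopy photos see blades
mostly face-on, and without this the sampler produces many uninformative
edge-on slivers.

A compound leaf is modeled as one simple polygon: an ellipse (width =
`width_ratio * length`) whose polar radius is modulated by a lobe harmonic
(one lobe per leaflet, amplitude `0.3 * lobe_depth`) and a serration
harmonic (amplitude `0.12 * serration_depth`, frequency at least 24).
Because the sum of deformation amplitudes stays below 1, the radius is
positive and the outline is star-shaped, hence simple — that is a
structural guarantee, and the test suite re-checks it with a brute-force
segment-intersection oracle. Out-of-plane bend and twist are progressive
rotations along the midrib, so `bend_angle = 0, twist = 0` is exactly
planar. Triangulation is ear clipping with lowest-index-first tie-breaking,
so the mesh is a pure function of the outline.

Leaflet counts and size distributions for the tomato model are not published
anywhere we could draw on; the preset ranges (3–7 leaflets, leaf length
0.28–0.42 of branch length, and so on) are this package's own estimates of a
plausible greenhouse tomato branch and are labeled as such.

## Leaf materials and disease

A texture stack carries the standard physically-based layers: RGB albedo,
tangent-space unit normals (+Z out of the leaf), ambient occlusion and
height, all generated from seeded multi-octave value noise plus a procedural
venation pattern (midrib plus curved laterals). `venation_amplitude`
controls all height variation, so setting it to 0 yields a perfectly flat
height layer and (0,0,1) normals — a degenerate limit the tests use.

Disease is applied as a *local* alteration: a family-specific continuous
intensity field is thresholded at the quantile that realizes the target
coverage, and only pixels above the threshold are touched. Four families
span the visual range of common foliar symptoms:

* `necrotic_spots` — point lesions with radial falloff, recolored dark
  brown and sunken in the height layer;
* `blight_blotch` — one spreading blotch with a chlorotic (yellow) rim
  grading into a brown core;
* `powdery_coating` — patchy pale coating that strictly raises masked-pixel
  luminance and height;
* `chlorosis` — diffuse low-frequency yellowing, color only.

Severity in $[0,1]$ is the single knob: target coverage =
`severity * family_max` with per-family maxima 0.25 / 0.5 / 0.7 / 0.9.
Because the threshold is a quantile of a continuous field, realized coverage
matches the target up to pixel rounding (the ±20% contract holds with large
margin) and is monotone in severity for a fixed seed. Severity 0 is the
healthy class and an exact identity. Early-stage disease corresponds to
severity ≤ 0.15; the iteration presets sample severity uniformly from
[0.15, 0.6], a visible-symptom range chosen a priori so that a 96-pixel
desk-scale render can still resolve lesions (at 4% coverage and desk
resolution a lesion is only a couple of pixels, which no classifier at this
scale could use).

## Rendering

Rendering is deliberately *not* path tracing: photorealism is expensive and,
as the development loop itself demonstrates, not the main quality driver.
Scenes are composited in a fixed order — procedural greenhouse backdrop,
optionally a second branch Gaussian-blurred with the preset's defocus sigma
(mimicking the cluttered, defocused canopy behind the subject), then the
foreground branch — using a painter's-algorithm rasterizer over the leaf
meshes with per-pixel Lambert shading:

$$\mathrm{color} = \mathrm{albedo} \cdot (\mathrm{ambient} + \mathrm{intensity}
\cdot \max(0, n \cdot \ell)) \cdot \mathrm{AO},$$

with tangent-space normals rotated by the leaf frame. `shade_leaf()` exposes
the same closed form on a flat texture and the tests compare both against a
brute-force per-pixel oracle. The height layer is generated and exported but
not consumed by the 2.5D shader (it exists for normal-map derivation and
for export completeness). The camera is orthographic, framed as a leaf-level
close-up with the branch deliberately overflowing the frame, plus random
zoom and offset. The label of a rendered image is defined by the generating
disease specification (infected iff severity > 0), never inferred from
pixels. Backdrops are procedural stand-ins for captured greenhouse
panoramas: sky-to-ground gradient, dark vertical row posts, a rail, clutter
noise and a green foliage tint; user PNGs are accepted as an alternative.
The whole scene assembly for dataset image $k$ is a pure function of
`derive_seed(master, k)`, which makes datasets byte-reproducible and image
$k$ independent of the dataset size.

## Augmentation regimes

Four registered modes: `none` (bit-exact identity), `weak` (zoom ±10%,
brightness ±10%, flips p = 0.5, rotation ±15°), `medium` (weak plus Gaussian
blur σ ∈ [0, 1.5], contrast ±20%, hue ±10°, additive noise sd 0.02), and
`strong` (all ranges doubled, rotation ±45°). The operator order is fixed —
geometric (flip, rotate, zoom) before photometric (brightness, contrast,
hue, blur, noise) — because blur and sensor-like noise should land on the
final geometry the way camera artifacts would. Parameters are drawn
uniformly from their ranges (the distributions are unstated upstream;
uniform is assumed and documented here). Rotation fills exposed corners by
edge replication so black corners cannot become a class give-away. The
concrete range values are this package's choices, not published numbers.

## The classifier and its training budget

No deep-learning framework exists in the supported environment, so the
package carries a small, fully tested CNN engine (BLAS-backed offset-loop
convolutions, exact backprop verified against finite differences). Two
architecture names are registered:

* `"paper"` — reserved for the full-scale published reference network
  (2,960,514 weights). Its exact layer list is not available in this
  distribution, so requesting it raises an error; we refuse to reverse-
  engineer layer widths to reproduce a printed weight count.
* `"compact"` — the desk-scale network all properties are validated on.

The compact architecture is designed around an unusually hard constraint:
it must learn from scratch, on one CPU, within five epochs over a few
hundred images at the stated learning rate of $10^{-4}$. Four choices make
that feasible, and each is standard in isolation:

1. **Informed stem initialization.** The first five stride-2 stem filters
   start as box opponent-color detectors (±(R−G), ±(G−B), luminance); the
   rest are He-normal. Browning and yellowing are the class signal, and this
   makes them first-class features from step one. All filters remain
   trainable.
2. **Multi-scale global pooling.** Every conv block is summarized by global
   average *and* global max pooling; the stacked vector feeds the head. Max
   pooling is what detects a localized lesion anywhere in the frame.
3. **Feature batch normalization.** The pooled vector is batch-normalized
   (running statistics at inference), so the zero-initialized head sees
   centered, unit-scale features — without this, a bias offset alone costs
   more optimizer steps than the whole budget provides.
4. **A fixed logit scale** (24, in the range normalized-softmax classifiers
   conventionally use): with unit-scale features and a small-norm head, raw
   logits would stay in cross-entropy's linear regime for the entire short
   budget; scaling lets the head express confident decisions and build a
   margin within a few hundred steps.

The optimizer default is Adam at the stated learning rate: measured on a
trivially separable toy problem, plain SGD at $10^{-4}$ moves the loss in
the fifth decimal over five epochs while Adam solves it; the stated rate is
characteristic of adaptive optimizers. Plain SGD remains available
(`hyperparameters(optimizer = "sgd")`). The dense head starts at zero, so an
untrained network outputs exactly uniform probabilities and ln 2 loss on a
balanced set. Epoch counts are unstated upstream; the default is 5 for
desk-scale runs, configurable. The mixed schedule (`iter6`) switches
augmentation mode at `ceiling(switch_fraction * epochs)`.

Bit-exact training reproducibility is promised only within one numeric
stack; tests assert tolerances, not golden weights.

## Test-time augmentation and the decision rule

A trained network evaluated naively is biased toward the healthy class.
`tta_score()` classifies R (default 32) randomly augmented replicates of an
image and reports the healthy-vote fraction; under mode `none` the network's
determinism collapses the score to exactly 0 or 1. The decision rule labels
an image infected when its healthy score falls strictly below the threshold
(default 0.8, i.e. more than 20% infected votes); a score exactly at the
threshold is healthy, following the published "below 80% … as infected"
wording. `calibrate_threshold()` searches the vote-fraction grid
$\{k/R, k = 1..R\}$ exhaustively (k = 0 is excluded since a zero threshold
is outside the rule's domain; intermediate values add nothing because scores
are vote fractions) and breaks ties toward the smallest threshold. The
worked arithmetic example — 26 of 29 images correct giving 89.6% — is
reproduced by `accuracy_report()` to one decimal.

## The synthetic world versus real greenhouses

Everything the tests establish is established *on the synthetic
distribution*. The generator emulates: compound-leaf branch close-ups,
cluttered defocused backgrounds, directional-plus-ambient greenhouse light,
four visually distinct foliar symptom types, and camera artifacts via
augmentation. It does not emulate: real leaf reflectance spectra, specular
highlights, shadows cast between plants, insect damage or mechanical injury
(false-positive sources), disease progression over time, or the full
variability of real greenhouse backdrops. A green validation accuracy here
therefore demonstrates that the pipeline, training function and evaluation
machinery work end to end at desk scale — it does not certify performance
on real photographs, which upstream required iterating the generator against
a real evaluation set that is not distributed.

## Numerical choices and degenerate inputs

* Severity-0 disease, zero-blur defocus, mode-`none` augmentation and the
  all-zero augmentation configuration are exact identities (bit-level).
* Lesion thresholds are field quantiles (type-7); coverage is exact up to
  pixel rounding; ties in continuous noise fields have measure zero.
* Ear clipping falls back to clipping a convex (then any) vertex if numeric
  degeneracy leaves no strict ear; outlines produced by the generator are
  star-shaped so the fallback is never exercised there.
* `decide()` at the threshold boundary returns healthy; calibration ties
  return the smallest grid threshold.
* Validation splits are exactly `round(0.1 n)` images, stratified with the
  healthy class receiving the extra image on odd counts.
* Training aborts with a diagnostic on non-finite loss rather than
  continuing silently.

## Known limitations

* The rasterizer has no depth buffer within a leaf (painter's order is per
  leaf), no anti-aliasing, and nearest-neighbor texture sampling.
* The compact network's accuracy under the five-epoch desk budget depends
  on the informed stem and scaled head described above; with pure random
  initialization the budget is insufficient, which is a property of the
  budget, not of the data.
* Costs in the development ledger are user-entered hours; the package does
  not attempt to meter human evaluation time.
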