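---
title: "How wheatspike detects spikes and heading time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How wheatspike detects spikes and heading time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatspike)
library(dplyr)
```

## The problem

In greenhouse phenotyping, single potted wheat plants are photographed daily
from several side-view orientations (here 0°, 45°, 90°). Two traits matter
for yield studies: the **heading time point (HTP)** — the first day the
spike (ear) is reliably visible, a proxy for growth stage BBCH55 — and the
**spike area** over time. Spikes are nearly the same colour as leaves, so
colour segmentation alone cannot find them; what distinguishes a spike is
its *texture*: the regular spikelet pattern produces high local
high-frequency energy, while leaf blades are smooth. The catch is that
*leaf crossings* — places where two leaves overlap — also produce compact
high-energy patches and are the dominant source of false spikes.

## The detection chain

`detect_spikes()` composes six stages; every intermediate is kept in the
result for audit.

1. **Plant mask (CIS).** The excess-green colour index `PP = 2g − r − b`,
   thresholded strictly at 0, separates plant from background
   (`color_index_segment()`). The index is invariant to adding the same
   offset to all channels, so achromatic lighting changes do not move the
   mask.

2. **Haar approximation image.** The grayscale image (BT.601 luma) is
   decomposed by a single-level 2-D Haar transform (`dwt_haar()`) with
   orthonormal filters (±1/√2). Only the half-resolution approximation band
   A feeds the texture stage: it concentrates the texture contrast while
   quartering the pixel count. Orthonormality makes energy conservation
   (`‖I‖² = ‖A‖²+‖H‖²+‖V‖²+‖D‖²`) a testable invariant; any other
   consistent scaling would only rescale features that the next stage
   re-normalises anyway. Odd dimensions are extended symmetrically by one
   row/column.

3. **Laws texture energy.** The A image is convolved with the eight
   zero-sum 3×3 Laws masks — all outer products of the level, edge and spot
   vectors L3 = (1,2,1), E3 = (−1,0,1), S3 = (−1,2,−1) except the non-zero-sum
   L3L3 — and each response is normalised to zero mean and unit standard
   deviation over a moving 25×25 window (`laws_features()`). The window
   normalisation is read as *local* (the classical texture-energy
   macro-window): a global z-score would ignore the stated window size.
   The local standard deviation is floored at 1e−6; flat regions yield
   feature 0. Responses are kept signed; convolution (kernel flipped) is
   used throughout, which only flips the sign of the two antisymmetric
   products — a distinction the classifier absorbs.

4. **Pixel classification.** An 8–10–2 feed-forward network (logistic
   hidden units, softmax output, cross-entropy loss; fit with `nnet` in
   warm-restarted segments with early stopping on validation loss, patience
   10 epochs, budget 500) labels each plant pixel of the A image as spike
   or non-spike from its 8 features (`train_classifier()`,
   `classify_image()`). Features are z-scaled with training-set statistics.
   Labelled pixels are split 70:15:15 (training:testing:validation),
   stratified by class, and the roughly 1:3.35 spike:non-spike imbalance is
   kept as is — no reweighting. The decision threshold is spike
   probability > 0.5.

5. **Leaf-crossing suppression.** The CIE L* channel is filtered with
   multi-scale Frangi vesselness (`frangi_multiscale()`, scales σ ∈
   {1,3,5,7,9}): the Hessian at scale σ (Gaussian derivatives, truncated at
   4σ, multiplied by the σ¹ normalisation prefactor), its closed-form
   eigenvalues ordered |λ₁| ≤ |λ₂|, and the bright-ridge response
   `exp(−R_B²/2β²)(1−exp(−S²/2c²))` with `R_B = λ₁/λ₂`,
   `S = √(λ₁²+λ₂²)`, zero wherever λ₂ > 0. β defaults to 0.5
   (the canonical choice) and `c` to half the maximum of S per scale (the
   standard data-driven rule); both are exposed in `spike_config()`. The
   response is thresholded at `tau_rel` times its maximum and every
   8-connected candidate component whose overlap with this vessel mask
   exceeds 50% is deleted whole (`suppress_crossings()`) — component-wise
   deletion rather than pixel subtraction, because subtraction leaves
   speckle.

6. **Spike reconstruction.** Candidates are intersected with the plant
   mask, opened with a disc of radius 2 to erase residual speckle, grown by
   geodesic dilation *inside* the plant mask for at most
   `max_geodesic_iter` iterations, opened again, and labelled into spike
   regions (`reconstruct_spikes()`).

### Phenology layer

`spike_present()` declares a spike present on a day when at least 2 of the
day's orientations each show at least 500 px of detected spike (inclusive
at 500). `detect_htp()` returns the earliest day from which presence holds
on *every* later observed day (persistence guards against false
emergences); an isolated early detection is skipped. Plants that never
qualify report day 0. A `gap_tolerance` knob (default 0, the strict
reading) can bridge isolated missing days. Presence is evaluated per day,
not cumulatively across days. `growth_series()` takes the per-day maximum
over orientations from the heading day; its relative day index starts at 1
on the emergence day. Agreement with ground truth is scored by standard
RMSE (`√(Σ(y−ŷ)²/n)` — root and mean included, since HTP errors are
reported on the day scale) and by R² as squared Pearson correlation (the
scatter-plot usage; `1 − SS_res/SS_tot` is available via `method = "ss"`).

## The scene simulator

Real glasshouse imagery for this task is not freely redistributable, so the
package ships a parametric simulator (`generate_scene()`,
`generate_series()`, `simulate_experiment()`) that reproduces exactly the
features the method depends on, with pixel-exact ground truth:

* **Leaves** are smooth Bézier ribbons (6 by default, width 6–10 px)
  fanning up from the pot area; layouts are redrawn (deterministically)
  until the requested number of distinct pairwise crossings exists.
* **Crossings** are rendered brighter than single leaves (overlap reflects
  more light), giving them the bright-ridge signature and the high texture
  energy that make them false-spike generators.
* **Spikes** are oriented capsules filled with a periodic speckle
  (period 6 px, grey-offset amplitude 0.22). The grey-offset modulation
  leaves the excess-green index of the spike body untouched, so the spike
  is plant to CIS but textured to the wavelet/Laws stage. Period 6 was
  chosen because the half-resolution A image samples the pattern at period
  3, which drives both the edge-type masks (whose taps sit two pixels
  apart and are blind to period-2 patterns) and the spot-type masks.
  The spike mean colour (0.24, 0.36, 0.26) keeps its coherent
  bright-ridge signal weak relative to crossings; its texture, not its
  brightness, is what the classifier must use — as in the real problem.
* **Background** is a desaturated blue-grey chamber wall (0.30, 0.25,
  0.40), excess-green margin −0.20, so CIS has a non-trivial job; additive
  Gaussian noise (sd 0.01) and a 0.4 px anti-aliasing band keep edges
  realistic while ground-truth masks remain deterministic (0.5-coverage
  threshold).
* **Time series** fix each orientation's canopy across days while the
  spike grows linearly in area from its emergence day, widening at a ~3:1
  length:width aspect anchored at its base (spikes grow upward).
  Occlusion is all-or-nothing per orientation-day, the simplest model of
  a spike hidden behind leaves.

What the simulator does *not* emulate: photorealistic spikelet geometry,
specular highlights, soil/pot clutter, partial occlusion, camera blur, or
the biological variation of real canopies. Tests passing on these fixtures
therefore demonstrate that the *algorithmic chain* behaves as designed
(texture contrast is detected, crossings are suppressed, the heading rule
is applied correctly) — not that the trained network transfers to real
glasshouse imagery; on real data the classifier must be retrained from
manually segmented images via `make_training_table()`-shaped inputs.

## Numerical and design choices

* **Vessel-mask threshold `tau_rel = 0.25`.** No binarisation rule is
  standard for the suppression mask. At the simulator's working
  resolution (192 px frames) spike widths of 14–36 px fall inside the
  σ ∈ {1,3,5,7,9} scale range, so a very permissive threshold (e.g. 0.15)
  marks nearly half the spike body as "vessel" and puts the component
  suppression rule on a knife edge; at 0.25 the mask still covers ~97% of
  crossing pixels while spike overlap stays near 0.3. On megapixel imagery
  with spikes far wider than the largest scale, lower values are
  appropriate; the parameter is exposed in `spike_config()`.
* **Reconstruction order and growth cap.** The opening runs *before* the
  geodesic growth as well as after, and growth is capped at 5 iterations
  by default. Growing first lets 3–6 px false-positive seeds balloon into
  leaf-sized blobs (a spikeless scene then reports thousands of false
  pixels); opening first erases sub-disc speckle, and the cap keeps
  area inflation into leaves that touch the spike at roughly 15% while
  still filling classification gaps inside the spike. Unbounded
  morphological reconstruction would flood through any touching leaf.
* **Hessian normalisation exponent.** The scale prefactor is σ¹ by
  default (`gamma = 1`), matching the filter definition used here; the
  canonical σ² is available via `spike_config(gamma = 2)`.
* **Ties and degenerate inputs.** Achromatic pixels (index exactly 0) are
  background; λ₂ = 0 pixels have zero vesselness; flat Laws windows yield
  feature 0; the multi-scale argmax keeps the first (smallest) maximising
  scale; 8-connectivity is used for components, so diagonally adjacent
  spikes merge.
* **Problem sizes.** The shipped tests and the acceptance script train on
  20 simulated 192×192 scenes (13 000 labelled pixels) and evaluate
  phenology on a 10-plant × 8-day × 3-orientation experiment (240
  images). These sizes give stable metrics (classifier accuracy ~95%,
  detection IoU ~0.84, HTP RMSE 0 days at the default settings) while a
  full run stays under a few minutes on one core.

## Known limitations

* The texture features are locally z-normalised, so a *noisy* flat region
  and a genuinely textured region both approach unit local variance;
  discrimination rests on the spatial coherence of the response within the
  25-window and on the contrast between window statistics near texture
  boundaries. Very noisy smooth leaves would erode the margin.
* Narrow early-stage spikes (width comparable to the leaf ribbons) sit
  closest to the suppression boundary — the same failure mode reported for
  texture-energy methods on real imagery.
* Spike *counting* is not validated (adjacent spikes merge under
  8-connectivity); the package reports region areas and totals only.
* The HTP rule is only as good as the persistence assumption: a plant
  whose spike is visible late and intermittently reports day 0 rather than
  a guess.
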