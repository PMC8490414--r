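---
title: "Confidence-map detection of individual palm trees: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-map detection of individual palm trees: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Mauritia flexuosa* (buriti) is a South American wetland palm whose rosette
crowns are visible in decimetre-resolution aerial RGB orthomosaics.  Mapping
each individual — a point per tree, not a bounding box — supports census and
monitoring work where crowns are dense, overlapping, and often clipped at
patch borders, conditions under which box detectors struggle.  `buriti`
implements a point-based detector: the network regresses a **confidence
map**, a per-pixel probability that a tree centre occupies that location,
and trees are read off as peaks of that map.

## Model

### Ground-truth confidence maps

Given annotated centres, the target map places a 2-D Gaussian kernel at each
centre, normalised to peak 1.  For map cell $p$ and centres $\{a_i\}$,

$$C(p) = \max_i \exp\left(-\frac{\lVert p - a_i\rVert^2}{2\sigma_t^2}\right).$$

Two choices here are genuinely open and are resolved as follows:

* **Overlaps combine by pointwise maximum, not sum.**  The network output
  is sigmoid-activated and thresholded as a probability; summed kernels
  would exceed 1 between close trees and break that reading.  (Summation is
  the usual choice in *counting-by-density* work, where the map integral,
  not its peaks, is the target — a different contract.)
* **Kernels peak at 1 rather than integrating to 1**, because the peak
  rule `C(p) > tau` operates on absolute probability values.

A fixed spread per stage is used for all trees; per-tree adaptive spreads
(e.g. proportional to crown size) are deliberately out of scope.

### The sigma schedule

The multi-stage module is supervised with a *schedule* of spreads: stage 1
uses the broadest kernel $\sigma_{\max}$ and the final stage T the sharpest
$\sigma_{\min}$, so early stages solve an easier, smoother regression and
the last stage pins the centre.  Only the endpoints are architecturally
pinned; interior stages interpolate **linearly** between them — the
simplest monotone schedule, exposed in `make_sigma_schedule()` so other
schedules can be swapped in.  Defaults are $\sigma_{\min} = 1$,
$\sigma_{\max} = 4$ map cells and $T = 4$, the best-performing combination
in the validation sweeps this design derives from.

### Architecture

* **Backbone**: eight stride-1 $3\times3$ conv + ReLU layers with filter
  counts 64, 64 | pool | 128, 128 | pool | 256, 256, 256, 256 — the first
  eight conv layers of VGG-19.  The two $2\times2$ max-poolings fix the
  prediction scale at 4 input pixels per map cell.
* **Pyramid pooling module (PPM)**: the feature map is adaptively
  average-pooled to $1\times1$, $2\times2$, $3\times3$ and $6\times6$
  grids; each pooled map passes a $1\times1$ conv reducing channels to a
  quarter, is bilinearly upsampled back, and is concatenated with the
  input features.  This injects global context and reduces sensitivity to
  crown-scale variation.  The bin set $\{1,2,3,6\}$ follows the standard
  pyramid-pooling design this module derives from.
* **Multi-stage module (MSM)**: stage 1 maps the PPM features through
  three $3\times3$ layers at 128 filters, one $1\times1$ layer at 512
  filters, and a final 1-filter layer with **sigmoid** activation.  Every
  later stage consumes the PPM features concatenated with the previous
  stage's confidence map and uses the same layer stack (the minimal
  consistent reading; whether stages share weights is unstated upstream —
  implemented unshared, with `share_stage_weights = TRUE` as an option).
  The sigmoid is applied at *every* stage, not only the last, because
  every stage is supervised against a probability-valued target.

### Loss

Stage $t$ contributes $f_t = \sum_p (\hat{C}_t(p) - C_t(p))^2$, summed (not
averaged) over map cells, and the total loss is $f = \sum_{t=1}^T f_t$.
Supervising every stage (intermediate supervision) keeps gradients flowing
into early stages of deep refinement chains.  Note the summed loss makes
gradient magnitude proportional to map area: learning rates tuned on one
patch size do not transfer unchanged to another.

### Peak localization

A map cell is a candidate tree if it is a **strict** local maximum over its
in-frame 4-neighbourhood (plateau ties are not maxima) and exceeds the
threshold $\tau$; accepted peaks then suppress any weaker candidate within
Euclidean distance $\delta$ (greedy, highest confidence first, ties broken
in row-major cell order for determinism).  Surviving cells map to input
pixels at the cell centre, $x = 4\,\mathrm{cell}_x + 2$.

The upstream description prints "$\tau$ equal to 1 pixel and $\delta$ equal
to 0.35", which is dimensionally inconsistent with its own definitions
($\tau$ bounds a probability; $\delta$ is a distance).  The package's
defaults therefore swap the assignment — $\tau = 0.35$, $\delta = 1$ cell —
and both are plain parameters of `peak_params()`.

### Evaluation

Detections and annotations are matched by **minimum-total-distance optimal
one-to-one assignment** (Hungarian algorithm) among pairs within a distance
gate, not greedily: optimal matching is deterministic and independent of
point order.  The gate defaults to 10 px ≈ one crown radius ≈ 1 m at 10 cm
GSD, and is data-dependent by nature, so it is exposed everywhere.
Precision, recall and F1 are micro-averaged over pooled TP/FP/FN; MAE is
the mean over evaluated images of the absolute count error, i.e. *trees
per image* (the per-image unit is an explicit choice — the upstream
definition does not say whether it pools per patch or per orthoimage).

## Synthetic scenes

Real survey orthomosaics of this kind are rarely redistributable, so the
package ships a generator whose scenes exercise the same failure modes:
radially shaded, speckle-textured circular crowns with a hue offset from a
cluttered background (low-frequency mottling plus non-target blobs in the
background hue), overlapping crowns, and crowns clipped at patch borders.
Crown centres are exact ground truth.  Scenes are deterministic in
`(spec, seed)`; datasets derive per-scene seeds from a master seed and
partition scenes by largest-remainder apportionment of the split
fractions, defaulting to the 42.3 / 34.5 / 23.2 train/validation/test
split of the survey design this emulates.

What the generator does **not** emulate: true Cerrado spectral signatures,
shadows and sun angle, other palm-like species, or georeferencing noise.
Passing the synthetic recovery experiments therefore demonstrates that the
pipeline — target rendering, optimisation, peak decoding, matching — is
implemented correctly and can recover known structure; it does not certify
real-world accuracy on survey imagery.

## Numerical choices and problem sizes

* The network stack (convolution via im2col + GEMM, pooling, bilinear
  resizing, backprop, SGD with momentum 0.9) is implemented in C++ on
  Armadillo; gradients are verified against central finite differences in
  the test suite.  ReLU subgradient at exactly 0 is taken as 0.
* Weights are He-initialised; each stage's final bias starts at −2.9
  (sigmoid ≈ 0.05) so the initial output matches the mostly-background
  targets and the first SGD steps do not saturate the heads.
* Annotations map to cells by nearest-cell rounding of `a / scale`;
  sub-cell target placement is omitted because the localization contract
  is ±1 cell anyway.
* Defaults mirror the published recipe (SGD, momentum 0.9, lr 0.001,
  100 epochs).  The packaged desk-scale experiments use a reduced
  configuration — channels 8,8 | 16,16 | 32,32, T = 2, 30 epochs,
  lr $10^{-5}$, $\sigma: 4 \to 1.5$ — chosen once on the validation split
  the way the original recipe tuned its learning rate; with the summed
  loss on 32 × 32 maps, $10^{-5}$ keeps the effective step of the same
  order as the published setting on full-size maps.  Problem sizes (50
  training scenes of 128 px, 20 held-out; a 2-point sweep grid at 64 px)
  are the package's chosen desk-scale defaults, small enough to run
  routinely yet large enough that a broken component cannot pass.
* Degenerate inputs: `n_stages = 1` renders at $\sigma_{\min}$ and the MSM
  reduces to its first head; empty annotation sets give all-zero maps and
  empty detection sets; `epochs = 0` returns the initialised model
  untouched; infeasible crown placements fail with a clear error after
  bounded rejection sampling.

## Known limitations

* CPU-only, single-device training; no mixed precision, no pretrained
  backbone weights are bundled (`pretrained` initialisation is a hook, not
  a shipped artifact).
* The tiling module drops residual mosaic margins rather than padding
  them, matching full-patch bookkeeping; trees in the margins are simply
  not evaluated.
* GeoTIFF geotransforms are supplied explicitly rather than parsed from
  raster tags; PNG input assumes an identity transform.
* Box-detector baselines (Faster R-CNN, RetinaNet) and wall-clock
  benchmarking are out of scope.
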