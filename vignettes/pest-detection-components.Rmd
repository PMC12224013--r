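---
title: "Methods: geometry, attention, augmentation and evaluation in pestkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, attention, augmentation and evaluation in pestkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestkit)
```

pestkit implements the bespoke components of a lightweight single-stage
detector for orchard pest imagery — a domain dominated by small, densely
distributed objects — in a form that can be exercised end-to-end on
synthetic data, without a GPU, a trained network, or an external dataset.
This vignette is the package's own account of the science: the models and
procedures, the parameters that matter, the numerical choices, and what the
passing test suite does and does not demonstrate.

## The point-line-distance box loss (PLDIoU)

Bounding-box regression losses in the IoU family penalize a prediction box
$C$ against a target box $G$ by $1 - \mathrm{IoU}(C, G)$ plus a geometric
penalty that keeps gradients informative when the boxes do not overlap.
The PLDIoU penalty is built from three points: the centers $C_{ctr}$ and
$G_{ctr}$ of the two boxes and the center $A_{ctr}$ of their minimum
enclosing box $A$. Let $l$ be the line through $C_{ctr}$ and $G_{ctr}$ and
$d$ the Euclidean distance from $A_{ctr}$ to $l$. Then

$$\mathrm{PLDIoU} = \mathrm{IoU} - \eta\, d^2, \qquad
  L_{\mathrm{PLDIoU}} = 1 - \mathrm{IoU} + \eta\, d^2,$$

with $\eta \ge 0$ a weight, default `10`. The penalty measures how
asymmetrically the enclosing box sits around the axis joining the two
centers: it is zero exactly when the three centers are collinear, which
happens in particular whenever the two boxes have equal width and height
(then $A_{ctr}$ is the midpoint of the segment). It grows when one box is
much larger than the other *and* displaced diagonally, the regime in which
single-stage detectors tend to emit oversized boxes.

### The sign in the line equation

For the line through $p$ and $q$ write $\alpha = q_y - p_y$,
$\beta = q_x - p_x$ and $\lambda = q_x p_y - p_x q_y$. A common way to
present the squared point-line distance is
$(\alpha x + \beta y + \lambda)^2 / (\alpha^2 + \beta^2)$, but with these
three coefficient definitions that numerator does **not** vanish at $p$ and
$q$ themselves: substituting $p$ gives
$\alpha p_x + \beta p_y + \lambda = (q_y - p_y)p_x + (q_x - p_x)p_y +
q_x p_y - p_x q_y = 2 p_y q_x - 2\,\mathrm{(cross\ terms)} \ne 0$ in
general. The expression that is zero at both defining points — and hence a
true squared distance to the line through them — is

$$d^2 = \frac{(\alpha x - \beta y + \lambda)^2}{\alpha^2 + \beta^2}.$$

`line_through()` and `point_line_penalty()` implement the corrected form;
the test suite checks at random lines that both defining points evaluate to
zero within 1e-9 after scaling.

### Numerical choices

* **Degenerate lines.** When the two centers coincide, $d$ is undefined and
  the penalty is 0 by convention (no center offset, no penalty). The
  degeneracy test is relative — centers closer than about $10^{-9}$ times
  the coordinate magnitude — because an exact-zero test lets rounding noise
  (e.g. after scaling both boxes by 3.5) produce an arbitrary near-vertical
  "line" and a wildly wrong penalty. This came straight out of a failing
  scale-invariance property and is the kind of guard any production IoU
  variant needs.
* **Raw vs normalized penalty.** As printed above, $d^2$ is in pixels², so
  at a 640-px training scale $\eta d^2$ can dominate the IoU term by orders
  of magnitude (the README example shows a loss of 60.95 for two
  plausibly overlapping boxes). The default keeps the raw pixel² form with
  $\eta = 10$, exactly as the loss is defined; `loss_config(normalize_penalty
  = TRUE)` divides $d^2$ by the squared diagonal of the enclosing box —
  the DIoU-style normalization — making the penalty scale-invariant and
  commensurate with IoU. Whether $\eta = 10$ was calibrated against a raw
  or a normalized penalty is not knowable from the loss definition alone,
  so both behaviors are exposed and tested.
* **No clamping.** PLDIoU can drop below $-1$ for distant boxes under the
  raw penalty; no clamp is applied.
* **Zero-area boxes.** IoU is defined as 0 when the union has zero area;
  all losses stay finite on degenerate annotations.
* **Gradients.** `pldiou_loss_grad()` returns the analytic gradient with
  respect to the eight corner coordinates. The loss is piecewise smooth
  (min/max switches at corner ties and at the overlap boundary); at those
  measure-zero kinks a one-sided subgradient is returned. The suite checks
  agreement with central finite differences to 1e-4 relative error at 100
  random pairs kept away from the kinks.

The independent oracles are deliberately primitive: IoU is checked against
counting raster cells on integer-corner boxes, and $d^2$ against a
coarse-to-fine nearest-point search along the parametrized line (window
refined to $\Delta t = 10^{-6}$, giving oracle error below $10^{-7}$ for
the coordinate ranges used).

## CBAM attention

The convolutional block attention module refines a feature map
$F \in \mathbb{R}^{C \times H \times W}$ in two sequential multiplicative
steps:

$$F' = M_c(F) \otimes F, \qquad F'' = M_s(F') \otimes F'$$

* **Channel attention** $M_c = \sigma(\mathrm{MLP}(\mathrm{AvgPool}(F)) +
  \mathrm{MLP}(\mathrm{MaxPool}(F)))$, with both poolings global over the
  $H \times W$ positions and a shared two-layer MLP ($C \to C/r \to C$,
  ReLU between, no biases — the standard CBAM choices, which the module
  definition itself leaves open). The reduction ratio `r` defaults to 16
  and must divide $C$; tests mostly use `r = 1`, where the identity-MLP
  closed form $M_c = \sigma(\mathrm{avg} + \mathrm{max})$ is exact.
* **Spatial attention** $M_s = \sigma(f^{7\times7}([\mathrm{AvgPool}(F');
  \mathrm{MaxPool}(F')]))$, with channel-wise pooled planes stacked along a
  2-channel axis and convolved with a single $7 \times 7$ kernel, stride 1,
  zero padding 3, one scalar bias — the padding is forced by the
  requirement that shapes be preserved. The stack order is average-first by
  default, matching the bracketed formula $[\mathrm{AvgPool};
  \mathrm{MaxPool}]$; descriptions of the module sometimes state the
  opposite order in prose, so `spatial_params(pool_order = c("max",
  "avg"))` makes the order explicit and configurable (the test suite
  demonstrates the two orders genuinely differ).

Because both attentions pass through a sigmoid, every weight is strictly in
$(0,1)$: the output never exceeds the input elementwise, and zero
parameters give the exact closed form $M_c = M_s = 0.5$, output $=$
$0.25\,F$. `apply_4cbam()` applies four independently parametrized modules
to four feature-map streams, the configuration used when attention is
inserted at four points of a detection neck; the exact insertion positions
inside a particular network are out of scope here, so the four-stream API
is the surface. Untrained parameters are drawn uniformly from
$[-0.1, 0.1]$ under an explicit seed so tests get reproducible,
non-degenerate weights.

## Augmentation with exact label remapping

All operators work on `annotated_image` objects (8-bit `H x W x 3` arrays
plus a label table) and remap boxes *exactly* through the same geometry the
pixels go through, then clip to the canvas and drop slivers (clipped area
below `min_box_area_px = 4` px², or either side below 2 px — stitching
margins otherwise produce unlearnable one-pixel boxes).

* **Mosaic (4)**: a jittered center point splits the output into a 2×2
  layout; each source is resized aspect-free to its cell.
* **Mosaic-9**: a 3×3 grid whose two interior x- and y-boundaries are
  jittered uniformly within $\pm\,\mathrm{jitter} \cdot \mathrm{out\_size}$
  of the even grid; every tile follows the same rule (resize-to-cell, same
  affine for labels). The grid realization is the package's own: the
  9-image operator is usually described only as stitching "by specific
  rules", and a jittered 3×3 partition is the deterministic reading that
  keeps tiles gap-free and overlap-free at jitter 0 — a property the suite
  asserts exactly.
* **Mixup**: $\lambda A + (1-\lambda) B$ in floating point, rounded
  half-up to 8 bits, labels the union of both lists. $\lambda \sim
  \mathrm{Beta}(8, 8)$ by default — tight around 0.5 so both images stay
  visible, since no mixing law is prescribed for detection mixup beyond
  "a ratio" — with `fixed_lambda` for exact tests. Execution probabilities
  (mosaic with probability 1.0, mixup with probability 0.5) are pipeline
  configuration, not operator behavior, and live in the CLI defaults.
* **Static transforms**: the offline dataset-expansion registry — size
  scaling, grayscale, center/random crops, crop-with-rescale, edge
  padding, rotation, horizontal/vertical flips, color dithering, affine.
  Geometric kinds remap boxes exactly; rotation and affine map a box to
  the axis-aligned bounding box of its four transformed corners (boxes
  stay axis-aligned, so rotated boxes grow — the standard convention).
  Photometric kinds never touch labels.

Resampling is nearest-neighbour with a fixed index mapping (output pixel
center $(i - 0.5)$ reads source pixel $\lceil (i - 0.5)\,s \rceil$). This
is a deliberate choice over filtered resampling: the augmentation contracts
are about *provenance* (which source pixel landed where) and *exact* label
arithmetic, both of which an interpolating resampler would blur away.
Every stochastic operator takes an explicit seed and is bitwise
reproducible.

## Anchor optimization

`fit_anchors()` clusters labeled-box `(w, h)` dimensions into `k = 9`
anchors with Lloyd iterations under either the detection-specific `"1-iou"`
distance — one minus the IoU of two boxes co-anchored at the origin, the
YOLO-family convention, and the default — or Euclidean distance.
Initialization is k-means++ under an explicit seed; `nstart = 10`
independent starts are run and the lowest final objective kept, the
standard guard against Lloyd's local optima (a single unlucky start on a
well-separated 9-cluster mixture was observed to merge two clusters and
miss a planted center by 200 px; with 10 starts recovery is sub-pixel
across seeds). Empty clusters are re-seeded to the farthest point.

The update step is chosen so that the recorded objective is provably
non-increasing: under Euclidean the centers move to the member mean and the
objective is the mean *squared* distance (the quantity the mean minimizes);
under 1-IoU the centers move to the member *medoid* — the member minimizing
total 1-IoU distance within its cluster — and the objective is the mean
1-IoU distance. A mean update under 1-IoU looks natural but minimizes
neither objective, and measurably increases it on random instances
(observed ~1e-3 bumps); the medoid update restores the k-medoids
monotonicity argument (initial centers are data points, so the old center
is always among the candidates) at the cost that anchors are actual
observed box dimensions, which is if anything a feature. Nine anchors are
grouped into three detection scales by sorting on area and chunking into
triplets.

Box dimensions are taken at native annotation resolution by default;
`rescale_to` applies an aspect-free rescale to a target training
resolution, since the resolution at which anchors should be clustered
depends on the training input size and is not implied by the annotations.

## Dataset IO and the two-stage split

Annotations round-trip through PASCAL VOC 2007 XML (the LabelImg dialect:
coordinates used verbatim as continuous corners, no one-pixel offset) and
YOLO text labels (`class cx cy w h`, normalized; conversion to corner
pixels is exact, round trips are within half a pixel of quantization).
The 12-class registry (Bd, elater, Er, Hh, PlA, PlL, Rs, Sb, Sc, slug,
snail, thrips) is a fixed bijection between names and indices 0–11;
unknown names are rejected with file-and-object context rather than
silently skipped.

`split_dataset()` implements the two-stage protocol used to prepare the
pest dataset: ids are shuffled under a seed, 2 of 10 parts become the test
set, and the remaining 8 parts are split 7:3 into training and validation —
target fractions 0.56 / 0.24 / 0.20. Counts are fixed by largest-remainder
rounding so the three parts always sum to `n` exactly; 6,000 ids yield
3,360 / 1,440 / 1,200. The split is a global random partition, not
stratified by class: only part-counts are specified by the protocol, and
per-class tallies are treated as descriptive.

## Detection evaluation

Matching is greedy and per-class: detections sorted by descending
confidence (ties broken by stable input order — documented because AP can
differ at ties) are each matched, within their image, to the unmatched
ground truth of highest IoU at or above the threshold (default 0.5, the
PASCAL convention). Matched detections are TP, others FP, unmatched ground
truths FN. From the cumulative counts, precision $P_c = TP_c/(TP_c+FP_c)$
and recall $R_c = TP_c/(TP_c+FN_c)$; AP is the area under the P-R curve
computed by all-point interpolation (the monotone non-increasing precision
envelope integrated over recall) — the direct reading of "area under the
curve", rather than the older 11-point approximation; mAP is the
arithmetic mean of per-class APs; $F_1 = 2PR/(P+R)$ at a confidence
operating point (default 0.25); mDT is the arithmetic mean of per-image
detection times. A class with detections but no ground truth gets AP 0
with a logged message.

The suite cross-checks the envelope integration against a brute-force
sweep that enumerates every confidence threshold and evaluates the
envelope definition by explicit counting. The two computations agree to
1e-9; note that a plain rank-by-rank Riemann sum is *not* the same
quantity whenever a later rank attains higher precision (e.g. flags
TP, FP, TP, TP), which is why the oracle evaluates the envelope rather
than the raw staircase.

## Synthetic fixtures: what they do and do not show

The generators are pure functions of spec + seed:

* `gen_scene()` renders colored ellipses on a noise-textured background,
  one label per ellipse, with an object-size law weighted 80% toward small
  objects (uniform sides 8–30 px, versus 40–120 px for the rest) so that
  well over 70% of boxes fall under the COCO small-object cutoff of
  $32^2$ px² — emulating the size profile of field pest imagery, where
  small objects dominate.
* `gen_planted_eval()` constructs detections and ground truths whose greedy
  matching reproduces a prescribed per-class TP/FP flag sequence exactly,
  together with the AP each sequence implies (computed by the brute-force
  sweep); the object is self-verifying through the full evaluation stack.
* `gen_box_pairs()` and `gen_anchor_mixture()` provide tagged box-pair
  geometries and truncated-Gaussian `(w, h)` mixtures for the loss and
  anchor suites.

What passing tests on these fixtures demonstrates: the geometry, losses,
attention arithmetic, label remapping, clustering and metrics are
implemented exactly as specified, at machine precision where closed forms
exist. What they do not demonstrate: anything about real pest photographs —
occlusion, blur, class imbalance, annotation noise, or how a trained
detector scores on them. Scenes are ellipses, not pests; headline
accuracies of a trained network are explicitly out of scope.

## Problem sizes and runtime

The test suite and the acceptance script are sized for a single CPU: oracle
comparisons use 100–200 random instances per property, feature maps up to
8×14×14, scenes up to 160 px, and anchor mixtures of 900 points. These
sizes were chosen so the closed-form and oracle checks are exercised well
past their edge cases while the whole suite runs in well under a minute;
none of the checked properties are size-dependent beyond that.

## Known limitations

* Image IO is PNG-only; in-memory operators are format-agnostic 8-bit
  arrays.
* CBAM is inference-only: no training, no gradient path through the
  attention parameters (the analytic gradient work is confined to the box
  loss, where it is the point).
* Mosaic-9's grid realization is one deterministic reading of a loosely
  specified operator; other readings (crop-based rather than resize-based
  tiles) would conserve labels differently.
* The anchor medoid update ties anchors to observed box dimensions; with
  very few boxes per cluster this is coarser than a mean.
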