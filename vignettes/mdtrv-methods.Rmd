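---
title: "Landmark detection and cephalometric measurement by multiresolution decision-tree regression voting"
author: "cephvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark detection and cephalometric measurement by multiresolution decision-tree regression voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephvote)
```

## The problem

Cephalometric analysis — locating named anatomical landmarks (sella,
nasion, orbitale, ...) on a lateral skull radiograph and deriving angular
and linear measurements from them — is the standard tool for orthodontic
diagnosis and treatment planning.  Manual annotation is slow and shows
substantial inter-observer variability, so a fully automatic pipeline has
three stages: landmark detection, measurement computation, and
anatomical-type classification.  `cephvote` implements all three, plus the
evaluation statistics used to benchmark them and a synthetic radiograph
generator that makes the whole pipeline testable without clinical data.

## The detection model

Detection is regression voting.  For a landmark $l$, a regressor is
trained to map the appearance of an image patch to the displacement
$\mathbf{d} = (d_x, d_y)$ from the patch center to the landmark.  At test
time many patches are sampled, each predicts a displacement, each predicted
position casts one unit vote into a pixel accumulator, and the accumulator
peak is the estimate.  Voting makes the estimate robust to individual
prediction errors without requiring a shape model or feature selection.

### Patch appearance: SIFT-style descriptors

A patch is the square window of side $2W + 1$ centered on a pixel.  Its
gradients $P_x, P_y$ are computed by central finite differences with
replicated borders; gradient magnitude and angle are

$$g_m = \sqrt{P_x^2 + P_y^2}, \qquad g_a = \operatorname{atan2}(P_y, P_x)
  \in [0, 2\pi),$$

with $g_a := 0$ where the gradient vanishes.  The window is partitioned
into a $4 \times 4$ grid of cells (boundaries at
$\lfloor (2W+1)\,i/4 \rfloor$), and each cell accumulates an 8-bin
orientation histogram in which every pixel deposits its full magnitude
into the single bin containing its angle.  The 16 histograms concatenated
row-major give the 128-long feature vector.

Three choices here were genuinely open and are worth recording.  We use
*hard* bin assignment weighted by magnitude — no trilinear interpolation,
no Gaussian windowing, and no normalization (an optional L2 normalization
is available but off by default).  This is the simplest reading of "8-bin
histogram of gradients", it makes the descriptor exactly conservative
(descriptor sum = patch gradient mass, which the tests exploit), and the
regression trees that consume the descriptor are invariant to any
monotone per-feature rescaling anyway.  Second, the angle convention is
the full-quadrant arctangent of $(P_y, P_x)$ in image coordinates
(y down), i.e. clockwise from the x axis on screen.  Third, a single $W$
is used at every resolution of the multiscale schedule, in that stage's
pixel units, so coarse stages see proportionally more anatomy.

### The regressor: CART with a split budget

Each (landmark, scale) pair gets one binary regression tree.  For node $t$
with observation weights $w_j$ (uniform $1/N$), the node error is the
weighted mean squared Euclidean displacement error
$\varepsilon_t = \sum_{j \in T} w_j \lVert \mathbf{d}_j -
\bar{\mathbf{d}}_t \rVert^2 / P_T$ with $P_T = \sum_{j \in T} w_j$, and a
split is scored by the reduction

$$\Delta\varepsilon_t = P_T\,\varepsilon_t - P_{T_L}\,\varepsilon_{T_L}
  - P_{T_R}\,\varepsilon_{T_R}.$$

Every observed value of every feature is a candidate threshold, routing
"strictly less goes left"; ties prefer the lowest feature index, then the
smallest threshold.  The scalar split criterion extends to 2-D targets as
the sum over components, which is the standard multi-output CART choice
and leaves the gain formula unchanged.  Growth is greedy best-first
(largest gain next) under a total budget `max_splits`; a node whose error
falls below `qed_tol` (default $10^{-6}$) times the root error is pure and
is not split.  Best-first growth makes trees nested in the budget, so
training error is provably non-increasing in `max_splits` — a property the
test suite checks.  Features are dense descriptors, so the missing-value
variant of the gain is not needed and is not implemented.  Postpruning is
likewise not implemented: depth is controlled by `max_splits` only, and
`select_max_splits()` chooses the budget by k-fold cross-validation over a
grid (default: powers of two up to the sample size, ties to the smallest
budget).

The pipeline default is `max_splits = 256`.  The value was fixed once from
a small cross-validation experiment on a synthetic training pool of the
size the benchmark produces (600 samples per landmark and scale), where
cross-validated displacement error was nearly flat between 64 and 512
splits; per-tree budget selection for all 76 + 152 trees of a model would
dominate training time for no measurable accuracy gain, so a single value
from the flat region is used for every tree.

### Multiresolution schedule and voting

The schedule runs at scales 0.125, 0.25, 0.5 and 1 (bilinear pyramid,
dyadic coordinate transfer).  At the coarsest scale, training patches are
sampled over the whole image ($K$ per image per landmark) and test patches
likewise ($K'$); at every finer scale, patches are sampled uniformly in
the $(2S+1) \times (2S+1)$ neighborhood of the true position (training) or
of the previous stage's estimate multiplied by 2 (testing).  Votes are
single units at `round(center + predicted displacement)`; out-of-bounds
votes are discarded; the estimate is the arithmetic mean of all cells
attaining the maximum count (ties averaged — a documented, deterministic
rule).  If every vote lands outside the image the stage falls back to the
image center and warns.  Accumulator smoothing is off by default (unit
voting); a Gaussian option exists because weighted voting is a documented
equal-performing alternative.

After the full-scale stage, the estimate is refined by an ensemble of $B$
trees (default 8) fitted on bootstrap resamples of the full-scale training
pool, all voting jointly over $K'$ fresh neighborhood patches.  This
ensemble-voting refinement keeps the role of a final forest-based voting
pass while remaining fully specified by the package's own primitives; it
is ablatable by setting $B = 1$.

Full-size cephalograms are first rescaled to a working width of 1960
pixels (`target_width`), with landmark coordinates multiplied and the
mm/pixel ratio divided by the same factor, so physical distances are
preserved.  Defaults at that width are $K = 50$, $K' = 400$, $W = 48$,
$S = 40$.

## Measurement geometry

All catalog entries reduce to five geometries ("plane" = line through two
landmarks in the 2-D radiograph):

* **angle of three points** — law of cosines at the vertex, clamped
  arccos, degrees in $[0, 180]$;
* **angle between two planes** — difference of line inclinations, each
  reduced to $(-90, 90]$, normalized to $(-90, 90]$.  The signed variant
  is primitive; unsigned entries take $|\cdot|$ at the catalog layer, and
  angles defined as the *rear lower* sector (the Z angle) take the
  supplement when the signed difference is negative;
* **distance between two points** — Euclidean pixels $\times$ ratio
  (mm/pixel);
* **distance from a point to a plane** — *signed* perpendicular distance,
  from the line form $y + k_1 x + k_0 = 0$; vertical planes use the
  general line form with "positive to the right" as the documented
  convention;
* **distance between two points projected to a plane** —
  $\sqrt{c_0^2 - (c_1 - c_2)^2} \times$ ratio with $c_1, c_2$ the signed
  point-to-line distances.  The signs matter: with absolute values the
  formula is wrong whenever the two points straddle the plane.  The tests
  verify the formula against the independent oracle
  $|(\mathbf{D}-\mathbf{C}) \cdot \widehat{\mathbf{AB}}|$.

Composites follow their published recipes: ODI and APDI as sums of plane
angles, FHI as the ratio of posterior to anterior face height (calibration
cancels), and MW with the sign rule on the x order of the incisal
landmarks.  The branch choice inside the composite sums deserves a note:
the signed inclination difference is discontinuous at $\pm 90°$, which is
exactly where the facial-angle term of APDI and the AB-to-mandibular-plane
term of ODI sit clinically ($\approx 85$–$90°$) — a pixel of landmark
noise can flip the sign and shift the composite by $\sim 180°$.  Those
large terms therefore use the *unsigned* angle (continuous across the
wrap, and the form used in the clinical definitions of these indices),
while the small tilt terms (palatal-to-FH, facial-to-AB) stay signed,
continuous around $0°$ where they live.  Catalogs ship as editable CSV files under
`inst/extdata` — 8 entries for the 19-landmark scheme, 27 for the
45-landmark scheme, 14 named planes — so role indices are data, not code.

Anatomical-type classification applies interval rules per measurement:
published normal ranges are closed, published strict inequalities strict, and
rules are evaluated in type order with the first match winning.  The
published ODI and MW rules do not tile the real line (e.g. the ODI normal
range $74.5^\circ \pm 6.07^\circ$ ends at $68.43^\circ$ but the open-bite
rule starts below $68.4^\circ$); a value in such a gap is labeled with the
nearest rule and flagged in the output, since no published convention
covers it.

## Evaluation statistics

Radial error is Euclidean pixel distance times the mm/pixel ratio; MRE is
its mean and SD the sample standard deviation with the $M - 1$
denominator.  SDR at precision $z$ counts errors *strictly* below $z$, as
a percentage; the default grid is 2.0, 2.5, 3.0 and 4.0 mm (the grid is
configurable).  SCR is the mean of the diagonal of the row-normalized
confusion matrix (rows = ground truth), with empty truth rows excluded
from the average.  MAE is the mean absolute difference between estimated
and ground-truth measurement values in the measurement's unit.

## The synthetic generator

`generate_synthetic_cephalogram()` renders, on a 490 × 600 canvas at
0.1 mm/px, bright smooth structures on a darker background: a cranial
vault ellipse arc, the facial soft-tissue profile spline, the mandibular
border, the palatal line, incisor bars, and rings at sella, porion and
orbitale, plus a localized density at every landmark locus.  Landmarks are
the very control points the curves pass through, so ground truth is exact
by construction.  Per-image shape variation is a global similarity
transform (translation ±12 px, rotation ±3°, log-scale ±0.04 — chosen as
plausible positioning and size variation for radiographs at this scale)
plus ±3 px of independent per-landmark jitter, applied identically to the
rendered structures and the stored truth; a linear illumination field and
additive Gaussian noise (sd 0.03 on the 0–1 intensity scale) complete the
image.

What the generator does *not* emulate: overlapping projected anatomy,
locally repeating structure (e.g. molar rows), exposure artifacts, and the
population-level shape variation of real patients.  Passing the synthetic
benchmark therefore demonstrates that the pipeline is implemented
correctly and can recover landmarks anchored to intensity structure under
moderate shape variation — it does not predict clinical accuracy on real
radiographs, which the original benchmarks put at MRE just under 2 mm.

## The desk-scale benchmark

`synthetic_benchmark()` runs the whole pipeline from one master seed:
25 seeded images (20 train / 5 test) at 490 × 600 with reduced detector
parameters $K = 30$, $K' = 200$, $W = 24$, $S = 20$ — the quarter-scale
analogue of the full-size settings, keeping a full train + detect cycle
around one to two minutes on a single CPU.  It reports per-stage MRE (the
coarse-to-fine schedule should improve the estimate from the 0.125 stage
to the full-scale stage), the mm-scale evaluation report, per-measurement
MAE between truth-derived and detection-derived catalog values, and the
classification agreement (SCR).  The acceptance script
`scripts/acceptance.R` recomputes exactly these quantities from scratch.

```{r benchmark, eval = FALSE}
bench <- synthetic_benchmark(seed = 0)
bench$report[20, ]          # dataset averages: MRE/SD (mm), SDR grid
bench$stage_mre_px          # per-stage mean radial error, working px
bench$measurements          # per-measurement MAE
bench$classification$SCR    # type agreement, percent
```

## Numerical choices and degenerate inputs

* Coordinates are 0-based throughout, x rightward, y downward; annotation
  files are one `x,y` line per landmark in scheme order, with a
  `one_based` loader flag for foreign files.
* Vote ties average the tied cells; split-candidate ties prefer the lowest
  feature, then the smallest threshold; cross-validation budget ties
  prefer the smallest budget.
* `acos` arguments are clamped to $[-1, 1]$; the projected-distance
  radicand is clamped at 0; degenerate geometry (coincident plane
  endpoints, zero-length angle sides) raises a typed error rather than
  returning NaN.
* All randomness (patch sampling, bootstrap resampling, fold assignment,
  synthetic shapes) derives from explicit seeds; `derive_seeds()` expands
  one master seed into independent child seeds below $2^{31}$, and the
  train + detect pipeline is bit-reproducible from a single integer.
* Patches overhanging a border are completed by edge replication, and
  coarse-stage patch windows may exceed the image — both are part of the
  descriptor definition, not error cases.

## Limitations

Detection quality depends on landmarks sitting on (or near) reproducible
intensity structure; landmarks defined on smooth or overlapped anatomy are
exactly the ones reported hardest in clinical benchmarks.  One tree per
(landmark, scale) keeps the model small but leaves single-tree variance to
be absorbed by voting and the final ensemble.  The package does not read
DICOM, does not detect calibration gauges (the mm/pixel ratio is supplied
per dataset), and implements no shape-model constraint — by design, since
the method's point is to work without one.
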