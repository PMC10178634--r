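---
title: "Methods: contrast enhancement, mid-value fusion and FPcRF feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast enhancement, mid-value fusion and FPcRF feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocad)
```

mammocad implements a desk-scale computational chain for mammography-style
computer-aided diagnosis: contrast enhancement, class-balancing geometric
augmentation, deep-feature extraction behind a pluggable contract, serial
mid-value feature fusion, flower-pollination-controlled regula-falsi
(FPcRF) wrapper feature selection, and a cross-validated evaluation
harness. Every stage runs on synthetic fixtures bundled as code, so the
whole chain is testable without any external image collection. This
vignette records the models, the tunable parameters, and the design
decisions taken where the method description left genuine freedom.

## Hybrid contrast enhancement

Mammograms are low-contrast: lesions sit a few intensity levels above a
bright, textured background. The enhancement stage combines a global
histogram remapping with local-statistics contrast stretching.

Stage 1 (global). For a grayscale image $\tilde\phi(x,y)$ with $L$ levels,
the per-level pdf is $p(\tilde\phi_k) = h_k / h$ (pixel counts over total)
and its cumulative sum $c(\tilde\phi_k)$ drives the remapping
$$F(\tilde\phi_k) = \tilde\phi_0 + (\tilde\phi_{max} - \tilde\phi_0)\,c(\tilde\phi_k).$$

Design decisions here:

* $\tilde\phi_0$ and $\tilde\phi_{max}$ are the *observed* minimum and
  maximum intensities, not the fixed nominal range. An already-windowed
  mammogram occupies a narrow band; mapping onto the observed range
  equalises the distribution without inventing dynamic range. A
  `fixed_range` switch restores the nominal $[0, L-1]$ target.
* A constant image has $\tilde\phi_0 = \tilde\phi_{max}$ and the mapping is
  ill-posed; it is returned unchanged.
* Real-valued pixels are binned to the nearest integer level for the
  histogram; the remapped values themselves stay real.

Stage 2 (local). With windowed local mean $\mu(x,y)$ and standard
deviation $\sigma(x,y)$ and the global mean $gm$ of $F$:
$$G(x,y) = \frac{K \cdot gm}{\sigma(x,y) + \beta}\,\bigl(F(x,y) - c\,\mu(x,y)\bigr) + \mu(x,y)^a.$$
The gain $Q = K\,gm/(\sigma + \beta)$ amplifies flat (low-$\sigma$)
neighbourhoods most; $\beta > 0$ keeps it finite everywhere.

* Defaults are $K = 0.8$, $\beta = 1$, $c = 1$, $a = 1$. The constants are
  conventionally hand-assigned in this family of methods and no canonical
  values exist; with $c = a = 1$ the formula reduces to classical adaptive
  contrast enhancement (stretch around the local mean), which is the safe
  canonical reading. Both $c$ and $a$ are exposed.
* The trailing term is read as exponentiation $\mu^a$; the alternative
  multiplicative reading $\mu \cdot a$ is selectable via
  `enhance_params(mu_term = "multiply")` because the source notation is
  ambiguous.
* Local statistics use a $7\times7$ window (no window is canonical; 7
  balances noise suppression against halo width at the 64–512 px scale)
  with reflect padding, and the population standard deviation.
* The output is clipped to $[0, L-1]$; range handling is otherwise
  unspecified in this method family.
* `contrast_stretch(..., Q_override = 1)` exists purely as an algebraic
  test hook: with $c = a = 1$ the transform is then the identity, which
  the test suite asserts exactly.

RGB input is collapsed with BT.601 luma weights (0.299, 0.587, 0.114)
before any of this. The whole chain is deterministic.

## Class-balancing augmentation

Mammography collections are small and unbalanced, so each class is grown
to a fixed target with three lossless geometric operations: horizontal
flip, vertical flip and counter-clockwise 90° rotation (the rotation
direction is a documented convention; the operations are exact index
permutations, so no interpolation artefacts enter).

The planner enumerates (source image, operation chain) pairs in rounds:
round 1 applies each single operation to every source; round $r$ uses
length-$r$ chains in lexicographic operation order, skipping any chain
equal *as a transform* to an earlier one. The three operations generate
the 8-element dihedral group of the square, so only 7 distinct
non-identity transforms exist — the deduplicated enumeration is
`flip_h`, `flip_v`, `rot90`, then `flip_h+flip_v` (180°),
`flip_h+rot90`, `flip_v+rot90` (the diagonal reflections), and
`rot90+rot90+rot90` (270°). Targets above $8\times$ the source count are
therefore necessarily reached by cycling the enumeration (the plan's
`copy` column records the pass); the alternative — refusing such targets —
would make the published bookkeeping unreachable. The final round is
truncated to land *exactly* on the target, using a seeded shuffle so the
truncation is deterministic yet unbiased. Published balanced counts are
exact (6000 or 4000 per class), so "at least" targets are implemented as
reach-then-truncate.

The stratified splitter assigns `floor(ratio * n)` items per class to
training (an arbitrary but fixed rounding rule) and is seeded. The
default ordering is augment-then-split, which reproduces the published
3000/3000-style bookkeeping; splitting first and augmenting only the
training side is available by calling the two functions in the other
order, since both operate on explicit inventories.

## Feature extraction contract

Downstream stages consume only an $N \times d$ feature matrix with
per-row labels and provenance tags (`backbone_id`, `source_id`). In the
full-scale method the matrix comes from the global-average-pooling layer
of a fine-tuned ResNet-style network ($d = 2048$); fine-tuning is
GPU-scale and needs external data, so this package deliberately ships no
training loop. Instead:

* `toy_backbone(seed, d)` is a deterministic stand-in: bilinear resize to
  $32\times32$, flatten, one fixed seeded random projection (no bias),
  `tanh` squashing. It is bit-reproducible, maps the zero image to the
  zero row, and supports any $d$ including 2048. Random projections
  preserve enough geometry that enhancement-induced differences survive
  into feature space, which is all fusion and selection need for testing.
* Any extractor producing fixed-length rows can be plugged in through the
  same `backbone_spec` contract.

## Serial mid-value fusion

Features from the original and the enhanced images are fused serially —
column-wise concatenation, $d = d_1 + d_2$ (for two 2048-wide extractors,
4096 columns). Concatenation keeps every feature, including redundant
ones, so a mid-value filter follows:

1. score every column (default: mean activation over rows; `max` and
   `median` are options — the per-feature statistic is not canonically
   defined, and the choice is recorded in the result);
2. threshold at the mid-value $F_{nc} = (lw + hw)/2$ of the lowest and
   highest column scores;
3. keep columns with score $\ge F_{nc}$ (boundary inclusive).

The maximum-score column always passes, so the retained set is never
empty. The retained indices, scores and threshold are all recorded in the
`fused_feature_set` for provenance.

## FPcRF feature selection

The selector searches binary column masks with a flower-pollination
optimizer over continuous positions $y \in [0,1]^d$, thresholded at
$\tau_0$ into masks (the continuous-to-binary encoding is not canonical;
thresholding at $\tau_0 = 0.5$ is the standard transfer-function-free
choice, and it is what makes the final threshold refinement meaningful).

Per iteration, each pollen takes one of two moves:

* global pollination (probability $p$):
  $y' = y + \vartheta\,L(\lambda)\,(y - B)$ with an independent
  heavy-tailed Lévy step per coordinate and $B$ the elitist best. The
  printed orientation $(y - B)$ is implemented as given; the textbook
  form $(B - y)$ is available via `fpcrf_config(canonical = TRUE)`.
* local pollination: $y' = y + \mu (y_z - y_k)$ with one
  $\mu \sim U(0,1)$ per update and $z, k$ drawn without replacement,
  excluding the pollen itself.

Positions are clipped to the unit box. Lévy steps use the Mantegna
sampler at $\lambda = 1.5$ (the density's printed normalisation is not
usable as stated, so the implementation targets the standard stable tail
$P(|s|>x) \sim x^{-\lambda}$ and the test suite verifies the tail index
empirically with a Hill estimator). A move is accepted only if the
fitness of its binarised mask improves on the pollen's own (greedy
acceptance — the common variant that guarantees the elitist,
non-increasing best-fitness trace). Equal-fitness ties prefer fewer
features, then the lexicographically smaller index set. The loop always
runs all configured iterations; there is no early stop.

The wrapper fitness is the stratified 5-fold cross-validated error of a
1-nearest-neighbour classifier (Euclidean) on the masked columns — the
"fine KNN" preset — with fold assignment seeded once per run. Five folds
keep the wrapper cheap; 10-fold is reserved for final evaluation.

Regula-falsi refinement: the method ends by root-finding on the
binarisation threshold. The refined threshold $V_n$ roots
$f(\tau) = \mathrm{fit}(\mathrm{mask}(B, \tau)) - \mathrm{fit}(\mathrm{mask}(B, \tau_0))$
over the bracket $[\min B, \max B]$ (the bracket description in the
source is ambiguous; min/max of the best vector is the reading under
which the step is executable). An 11-point scan locates a sign change for
the false-position iteration
$$V_1 = \frac{r_1 f(r_2) - r_2 f(r_1)}{f(r_2) - f(r_1)},$$
iterated with bracket maintenance. When no sign change exists the scan's
arg-min is used instead, and the final threshold is chosen among the
scanned points, $\tau_0$ and the root by lowest fitness — so the refined
mask can never be worse than the mask at $\tau_0$. A (near-)constant best
vector degenerates to $V_n = \tau_0$.

Defaults ($n = 20$ pollens, 50 iterations, $p = 0.8$,
$\vartheta = 0.01$) follow common flower-pollination practice; all are
exposed in `fpcrf_config()` and echoed into every result for
reproducibility.

## Evaluation harness

`kfold_evaluate()` aggregates out-of-fold predictions from seeded
stratified folds into one confusion matrix; `compute_metrics()` derives
accuracy, Cohen's kappa $(p_o - p_e)/(1 - p_e)$, the multi-class Matthews
correlation coefficient (generalised correlation form), and
macro-averaged precision, sensitivity, F1 and FPR (macro-averaging is a
documented choice for the 3-class case, where a single printed number per
metric does not determine the averaging rule). All metrics are reported
in percent except FPR, which stays a fraction. Per-class metrics with a
zero denominator are set to 0 and flagged rather than propagating NaN.
Wall time is recorded but never asserted — it is hardware-dependent.

The classifier registry approximates familiar point-and-click presets:
cubic/quadratic/linear/RBF SVMs (polynomial kernels use $coef_0 = 1$,
the inhomogeneous form — the homogeneous one is sign-blind at even
degrees), 1-NN, and small feed-forward networks. The bundled network
implementation has a single hidden layer, so the "bi/tri-layered"
presets are approximated by width; exact preset parity with any external
toolbox is not promised.

`margin_of_error()` implements the standard normal-quantile half-width
$z \cdot s/\sqrt{n}$ around the sample mean ($z = 1$ at 68.3 %, 1.960 at
95 %), taking the value list explicitly: published analyses of this kind
are often ambiguous about which values entered, so the operation makes
the sample explicit instead of guessing.

## Synthetic fixtures, and what passing tests show

`make_images()` renders low-contrast backgrounds with additive Gaussian
blobs (plus radial spikes for the "malignant" class, a crude spiculation
analogue) and ground-truth masks. `make_features()` plants
class-informative Gaussian columns (class means `effect` within-class
standard deviations apart) among standard-Gaussian noise columns, with
the planted index set recorded. Both are bit-reproducible under their
seeds.

These fixtures emulate the *contracts* of real data — low contrast,
bright localised structure, a known informative subspace — not the
statistics of real mammograms or of trained GAP features (no tissue
texture, no spatial correlation of noise, Gaussian rather than
rectified-activation feature distributions). Green tests therefore
demonstrate that each operation implements its stated mathematics and
that the selector can recover a planted informative subspace; they are
not evidence about clinical accuracy on real collections.

`planted_recovery_benchmark()` reports two error deltas versus the
all-features baseline: `improvement` uses the selector's own CV fitness —
the quantity the algorithm actually optimises — while
`holdout_improvement` re-measures both masks on an equally sized set of
rows the selector never saw. The internal delta is optimistically biased
by construction (the optimizer can exploit quirks of its own sample); the
hold-out delta is the honest generalisation measure, and under a
zero-effect generator it is centred on zero, which the test suite checks
with a sign test.

## Problem sizes and numerical choices

The test suite runs the recovery benchmark at $d = 50$ (5 informative),
100 samples per class for selection plus 100 held out, 10 seeds, and the
exhaustive-subset cross-check at $d = 8$ over 5 seeds, where all
$2^8 - 1$ masks are enumerable; the end-to-end pipeline check uses 18
images of $64\times64$. These sizes were chosen so the full suite is a
minutes-scale desk run while keeping the statistical checks meaningful.
Tolerances: the pixel-loop enhancement oracle agrees to $10^{-9}$
(pure floating-point reordering); regula falsi is compared with bisection
at $10^{-8}$; statistical checks (Hill tail index in $[1.2, 1.8]$ at
$10^5$ draws, chance-level error within 0.15) use wide bands because they
are finite-sample estimates.

## Known limitations

* No denoising, pectoral-muscle removal or ROI segmentation — the
  enhancement chain is the whole preprocessing step.
* No training loop: the deep-feature stage is a contract plus a toy
  backbone; published headline accuracies on real collections depend on a
  fine-tuned network and are out of reach (and out of scope) here.
* JPEG I/O is not bundled; PNG and TIFF are.
* The wrapper fitness re-evaluates a 1-NN cross-validation per candidate
  mask, so runtime scales with population × iterations × $N^2$; the
  defaults are sized for feature matrices up to a few hundred rows and a
  few thousand columns.
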