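---
title: "slidemil: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slidemil: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Slide-level outcome labels (did the tumor recur?) attach to a whole
pathology slide, not to any of the hundreds of tiles it is cut into.
Many tiles of a high-risk slide look perfectly benign, so training a
tile classifier on inherited labels poisons the supervision. slidemil
implements the multiple-instance view: all tiles of one slide form a
*bag* with a single label, a shared backbone scores each tile, and a
bag-level aggregate is supervised. Around that core it provides the
standard preprocessing (tiling, stain normalization, a nuclei heatmap
as a fourth channel) and the survival statistics used to validate any
such risk marker on censored follow-up data.

## Model and objective

Per-tile scores $s_i$ are aggregated by the signed generalized mean
$S = \operatorname{sign}(g)\,|g|^{1/p}$ with
$g = \sum_i \operatorname{sign}(s_i)|s_i|^p$, which for non-negative
scores is the plain $p$-norm $(\sum s_i^p)^{1/p}$. At $p = 1$ it is the
sum, as $p \to \infty$ it approaches the maximum; the default $p = 3$
sits between "average evidence" and "worst tile wins", which is the
behaviour MIL needs when only a fraction of tiles carry signal. Signed
powers extend the expression to the raw (unbounded, possibly negative)
scores a linear head emits; an optional `power_mean` flag gives the
$(\frac1n\sum s^p)^{1/p}$ variant. The aggregate is computed in a
max-rescaled form so large exponents cannot overflow.

The sigmoid-activated bag score $a = \sigma(S)$ is thresholded at
$t = 0.4457$ and mapped to a class probability by a continuous,
strictly decreasing piecewise-linear transform with $p(0) = 1$,
$p(t) = 0.5$, $p(1) = 0$. Note the orientation: *high* activated scores
map to *low* probability, so with cross-entropy the label $y = 1$ must
denote the good outcome (low risk). The package states this convention
once, in `mil_config()`/`generate_bag()`, and uses it everywhere; the
reported risk score is the activated value $a$ and
`predicted_class = 1` flags $a > t$ (ties at exactly $t$ go to the
low-score class; the event has measure zero but the rule is fixed for
determinism). The training objective is cross-entropy on the
transformed probability plus $\alpha \sum w^2$ over all trainable
weights ($\alpha = 0.02$); probabilities are clipped to
$[10^{-7}, 1 - 10^{-7}]$ because the transform genuinely reaches 0 and
1 at the endpoints.

## Optimization

The learning-rate schedule (1e-4, halving every 10 epochs) and the bag
batch size of 1 are fixed protocol; the optimizer is a design choice and
slidemil uses Adam, with one deliberate refinement: the L2 term enters
as decoupled weight decay ($w \leftarrow w - \mathrm{lr}\cdot 2\alpha w$
before the Adam update of the data gradient) rather than being added to
the gradient that Adam normalizes. Pushing $2\alpha w$ through Adam's
per-parameter normalizer makes the decay dominate every weight whose
data gradient is small — at $\alpha = 0.02$ this demonstrably collapses
the small backbone to the majority class (a supervised probe on the
same tiles reaches 0.997 accuracy without the penalty and 0.75 with it
in normalized form, against 1.0/0.997 with decoupled decay). Decoupled
decay applies exactly the objective's gradient, scaled by the learning
rate, and is the standard resolution of this pathology. Reported losses
always use the full objective verbatim.

A practical note on scale: the aggregation, sigmoid and transform
together attenuate per-tile gradients by roughly a factor 20, and the
fixed learning rate bounds each Adam step, so bag-level learning
reliably takes off only after one to two thousand optimizer steps
(bags × epochs). Cohorts of a few dozen bags trained for the default
20 epochs stay at chance; the shipped benchmarks use 120 training bags
for exactly this reason.

## The conv-net engine

No deep-learning framework is assumed: the package ships a compact,
deterministic CPU engine (Rcpp/RcppArmadillo) providing im2col-based
convolutions (including grouped/depthwise), per-channel affine
normalization parameters, ReLU/ReLU6/sigmoid, 2×2 max-pooling,
nearest-neighbour upsampling, and Adam. Two topologies are built on it:

* a U-net (encoder–decoder with skip connections, per-pixel sigmoid) for
  nuclei segmentation, default depth 4 / base 16 channels, with depth 3
  / base 8 used throughout the tests for speed;
* an inverted-residual (MobileNetV2-style) per-tile scorer whose stem
  accepts 4 channels and whose single-unit linear head emits the raw
  tile score. The `standard` variant follows the published topology at
  width 1.0 (verified in the tests against an independent parameter
  count from the block table); the `tiny` variant (3 stages at roughly
  quarter width, expansion 4, ~8k parameters) exists so that training
  finishes in minutes on one CPU.

Weight initialization is He-normal from a private xorshift RNG, so a
seed fully determines a model; batch-normalization statistics are
replaced by learnable per-channel affine parameters, which at batch
size 1 is the honest choice (there is no batch to normalize over).
Published pretrained weights are three-channel and would not fit the
four-channel stem anyway, so all training starts from seeded random
initialization.

## Nuclei heatmaps

The U-net trains with Dice loss (smoothing ε = 1e-8) on any
image/mask pairs; augmentation is horizontal/vertical flips only, Adam
at 1e-3. Validation Dice is computed on the *soft* predictions,
consistent with the loss, and heatmaps are never thresholded anywhere in
the pipeline: the soft values around nuclei (cytoplasm, cell shape)
carry information the classifier may use. `evaluate` reports soft Dice
as primary.

## Stain normalization

RGB is mapped to optical density $OD = -\log_{10}((I+1)/256)$ and
modelled as $OD \approx C\,W$ with a 2×3 non-negative unit-row stain
basis $W$ and non-negative concentrations $C$. The basis is estimated at
robust angular extremes (type-1 quantiles at 0.5% / 99.5%, so a
duplicated tile set yields the identical profile) of the pixel
directions within the 2-D singular subspace of the OD cloud. A sparse
(L1, default weight 0.1) NNLS solve gives concentrations during
estimation. We considered alternating sparse-NMF refinement of the
basis and rejected it: without near-pure pixels the factorization is
not identifiable, and on construct-and-recover experiments the
refinement *lowered* the penalized objective while moving the basis
away from the truth (from ~3° to ~7° error). The cone-edge estimate
recovers known bases within a few degrees. At transformation time
concentrations are solved without the sparsity penalty, so
self-normalization is lossless up to rank-2 model error; per-stain
scales are matched at the 99th concentration percentile, and white
pixels (zero OD) stay white. The packaged reference profile is
estimated deterministically from a synthetic reference tile at first
use; normalization is applied after resizing (cheaper, equivalent up to
resampling).

## Tiling

Tiling is a regular grid, stride defaulting to the tile size
(non-overlapping); coordinates are 0-based half-open pixel intervals. A
tile is kept when at least `tissue_threshold` (default 25%) of its
pixels fall below the whiteness cutoff (mean RGB 220) — the threshold
the original protocol used is unstated, so both numbers are exposed
configuration. Resizing is bilinear and rescales the microns-per-pixel
metadata by the size ratio.

## The synthetic generator

The generator defines the study conditions for every test. Tiles are an
eosin-like textured pink background with rotated elliptical nuclei;
the binary mask is 1 exactly on nucleus interiors. Four morphology axes
distinguish the high-risk "signal" tiles: larger nuclei (major radius
9–14% vs 5–8.5% of the tile edge), darker nuclei (intensity 50–105 vs
115–165 of 255; hyperchromasia), higher eccentricity (axis ratio
0.35–0.7 vs 0.7–1.0; atypia), and oriented low-frequency fibrous
stroma bands (probability 0.6 on signal tiles). Immune cells are small
round dark dots, four expected per background tile and a quarter of
that on signal tiles, so infiltration marks low risk. A high-risk bag
contains `ceiling(signal_fraction × n_tiles)` signal tiles (default
half — deliberately far from all, to exercise MIL's tolerance of
label-conflicting tiles); low-risk bags contain none. Bags attach the
ground-truth mask as the oracle fourth channel by default, so the MIL
stage can be studied independently of segmentation quality; the
pipeline instead uses the trained U-net's heatmaps. Every tile records
whether it is a signal tile, enabling provenance-based oracles
(ranking enrichment, null AUC).

Survival cohorts follow a Weibull proportional-hazards model
(default shape 1.2, scale 36 months — a realistic post-resection
recurrence scale) with a binary marker and an ordered three-level stage
covariate; every subject records its true linear predictor. Censoring
is uniform on $(0, c_{max})$ with $c_{max}$ solved by bisection so the
expected censored fraction hits the target (realized fractions land
within ±0.05 for cohorts of a few hundred subjects or more).

What the generator does *not* emulate: real H&E texture and scanner
artifacts, nucleus clustering/overlap, within-slide spatial
correlation, informative censoring, and competing risks. Green tests
therefore demonstrate that the machinery is correct and that the
training dynamics work at desk scale — not that the classifier reaches
any particular performance on clinical slides.

## Survival statistics

Kaplan–Meier, log-rank and Cox (Efron ties, Wald intervals) wrap the
survival package. Time-dependent ROC at horizon τ uses the
cumulative-case / dynamic-control definition with
inverse-probability-of-censoring weights from the Kaplan–Meier estimate
of the censoring distribution (case weight $1/\hat G(T^-)$); the AUC is
the trapezoid under the resulting curve and equals the weighted
case/control rank-sum with ties counted ½ — with no censoring before τ
it is exactly the Mann–Whitney statistic. "Accuracy at the best Youden
index" maximizes $Se + Sp - 1$ over cutoffs (ties resolved toward the
smallest cutoff) and weights $Se$ and $Sp$ by the KM event probability
at τ, which is censoring-consistent; because the naive complete-case
accuracy differs under censoring, both are returned and the adjusted
one is primary. The category-free NRI estimates event probabilities by
τ with KM *within* the up- and down-reclassified groups, reducing to
the textbook counting formula when censoring is absent; confidence
intervals are a seeded percentile bootstrap (default 1000 resamples).
No multiple-testing correction is applied anywhere; users comparing
many markers and horizons should correct externally.

## Numerical and degenerate-input choices

* Aggregation at $g = 0$ (signed powers cancelling) returns $S = 0$
  with zero gradient.
* `continuous_nri` with entirely tied risks warns and returns 0; a
  degenerate event probability at τ (0 or 1) is an error.
* Stain estimation on fewer than 20 non-white pixels is an error;
  `normalize_color` on an all-white tile is the caller's degenerate
  case (estimation fails, normalization of white pixels is exact).
* `extract_tiles` on an undersized image warns and returns an empty
  list rather than erroring, so batch jobs skip rather than abort.
* U-net inputs must be divisible by $2^{depth}$; this is checked, not
  padded, to keep heatmap/tile alignment exact.

## Problem sizes in the shipped tests

The acceptance-style tests train the depth-3/base-8 U-net on 200
synthetic 64-px pairs for 10 epochs (held-out soft Dice ≥ 0.80; in
practice ≈ 0.999), and the tiny backbone on 120 bags of 16 four-channel
64-px tiles for 20 epochs, evaluated on 40 held-out bags (accuracy
≥ 0.90, and 0.5 ± 0.15 when the generator carries no signal). The
end-to-end determinism check runs the full pipeline twice at smoke
scale (32-px tiles, a few slides) and compares outputs byte for byte.
These sizes were chosen so the whole suite runs in well under half an
hour on a single CPU while still exercising real training dynamics.

## Known limitations

* The engine is double-precision, single-threaded CPU code: fine for
  the tiny/desk-scale variants, not for 224-px slides at cohort scale.
* Training cannot resume mid-run (optimizer state is not serialized);
  models themselves round-trip exactly through `saveRDS`.
* The standard backbone variant is provided and shape/parameter-count
  verified, but the shipped tests train only the tiny variant.
* Time-dependent metrics assume censoring independent of the marker;
  the NRI bootstrap resamples subjects, not slides-within-patients.
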