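---
title: "Quality-weighted tissue-based multiple instance learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-weighted tissue-based multiple instance learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemil)
library(dplyr)
```

## The problem

Whole-slide renal biopsy images carry labels only at the slide level — a
delayed-graft-function outcome, an acute tubular injury grade, a Remuzzi
component — while the information lives in individual tissue compartments:
tubules, glomeruli, vessels and cell nuclei. Multiple instance learning
(MIL) treats each slide as a *bag* of unlabelled *instances* and learns a
bag-level predictor. Two failure modes dominate in practice: segmentation
artefacts produce instances whose features mislead the bag predictor, and
small biopsies (below the Banff adequacy rule of seven glomeruli and one
artery) contribute noisy labels.

`tissuemil` implements a complete pipeline addressing both: ensemble
segmentation fusion with an uncertainty penalty, per-instance segmentation
*quality weights*, gated soft-attention bag classification with optional
quality weighting, tissue-count-weighted evaluation, and visualisation
confined to tissue outlines. Because clinical slides are access-restricted,
the package ships a synthetic slide and bag generator with analytic ground
truth; the generator is first-class, tested code and is the package's
acceptance surface.

## Model

### Gated soft attention

Each instance's feature vector \(x_k\) is embedded as
\(h_k = \tanh(W_1 x_k + b_1)\). The attention weight of instance \(k\) in a
bag of \(K\) instances is

\[
a_k = \frac{\exp\{w^\top(\tanh(V h_k^\top) \odot \mathrm{sigmoid}(U h_k^\top))\}}
           {\sum_{j=1}^{K} \exp\{w^\top(\tanh(V h_j^\top) \odot \mathrm{sigmoid}(U h_j^\top))\}},
\]

with learnable \(w, U, V\); the sigmoid gate restores sensitivity where
\(\tanh\) is flat near zero. The bag representation is the attention-weighted
average \(z = \sum_k a_k h_k\) and a softmax head maps \(z\) to class
probabilities. An un-gated variant drops the sigmoid branch. The classic
max-pooling MIL baseline (per-instance probabilities, bag score by max) is
implemented for comparison; it is the most artefact-sensitive aggregator
because a single misleading instance determines the bag score.

### Ensemble fusion and the quality weight

Given per-model, per-class probability maps from any segmentation ensemble,
the fused map is

\[
\tilde p = \max(\bar p - A\,\sigma_p,\, 0),
\]

where \(\bar p\) and \(\sigma_p\) are the per-pixel across-model mean and
standard deviation and \(A \ge 0\) is a penalty chosen on training data
(`sweep_penalty()` maximises instance-level Jaccard). Pixels on which the
ensemble disagrees are suppressed, which removes single-model false
positives. We use the population convention for \(\sigma_p\) (divide by the
model count): the ensemble is the full model set, not a sample from a larger
one; a `sd_type` switch restores the sample convention.

Instances are extracted from \(\tilde p\) by a max-flow/min-cut binarisation:
unary costs \(-\log \tilde p\) vs \(-\log(1-\tilde p)\) (clamped at
\(10^{-6}\)), a Potts pairwise term on the 4-neighbour grid, 8-connected
components, minimum area 32 px at 0.44 microns per pixel. At zero smoothness
the cut equals 0.5-thresholding, which the tests exploit as an oracle. For
large maps an exact reduction fixes every pixel whose unary log-odds margin
exceeds the largest possible neighbour influence (\(4\lambda\)) and solves
the flow only over the ambiguous band; the reduction provably preserves the
optimal labelling and is validated against the full graph in the tests.

For a slide with \(K\) instances, \(s_k\) is the mean of \(\sigma_p\) over
instance \(k\)'s mask (on the instance's own class channel) and

\[
g_k = \frac{\max_j s_j^2 - s_k^2}{\max_j s_j^2 - \min_j s_j^2} \in [0, 1].
\]

The most consistently segmented instance of a slide gets \(g = 1\), the most
contentious \(g = 0\). When all \(s_j^2\) are equal — including the
single-instance slide — every \(g = 1\): equal evidence quality should not
down-weight anyone. Quality-weighted attention multiplies each raw attention
score by \(g_k\) *before* the softmax; with all \(g = 1\) it reduces exactly
to plain attention. The printed form of the weighted attention denominator
reuses the numerator's own index; we normalise over \(g_j\) so the weights
sum to one, and keep the literal variant behind
`attend_weighted(..., denominator = "gk")` for comparison. Following the
combined scheme, `use_quality_weights` applies \(g\) at both training and
test time and `include_g_feature` additionally appends \(g\) as a feature
column; flags allow either alone for ablation.

## Features

`handcrafted_features()` covers every family a compartment-based reading
needs, with physical units from the microns-per-pixel scale:

* **morphology** — area (um^2), perimeter, eccentricity (from central
  moments), solidity (area over convex-hull area, hull taken over full pixel
  extents), enclosed-cavity ("lumen") area found as background holes inside
  the mask, lumen-to-total *area* ratio (a ratio of areas, not diameters, so
  no geometric template is fitted), and a urinary-space analogue
  (convex-hull minus mask minus cavities). The boundary of a glomerulus is
  annotated inconsistently even by experts, so the hull-based proxy is a
  stated stand-in rather than a claim about capsule anatomy.
* **colour** — per-channel mean/SD inside the mask plus boundary-band minus
  interior contrasts (band = mask minus a 3 px erosion at 0.44 mpp), a
  second-order statistic of how colour distributes across the compartment.
* **texture** — gradient-magnitude mean/SD inside the mask.
* **nuclei** (PAS only; invisible under Sirius Red) — count, density, and
  nucleus darkness (mean luminance; darker nuclei accompany mitosis and
  repair) and nucleus-to-boundary distance (distance-transform value at the
  centroid; distant nuclei suggest cytoplasm expansion), each pooled at
  every tenth percentile, 0th–100th inclusive (11 values; a `10-90` grid is
  available). Percentile pooling is less artefact-sensitive than max
  pooling. Instances without nuclei get *missing* values, not zeros.
* **slide level** — the total biopsy area appended to every instance.

The schema (43 PAS / 19 SR columns) is pinned in `feature_schema()`; the
grouping, not the exact count, is the contract. Deep features are average
pooled from a pluggable extractor's spatial map with the crop at native
size, so objects of equal physical size elicit equal filter responses;
undersized crops are padded reflectively and flagged.

Imputation (nuclei-group missingness) and zero-mean/unit-variance
normalisation are fitted on the training split only and applied frozen to
validation and test data. Pooling statistics over all data is available
via `scope = "global"`, but the default guards against leakage. Population SDs are used; the sample
convention is a switch.

## Training protocol

One bag per optimisation step (Adam, manual backpropagation through the
gated attention), bags sampled with probability inversely proportional to
their class frequency so rare grades are seen as often as common ones.
Training stops 40 epochs after the validation AUC stops improving by more
than `1e-4` (both are `mil_config()` fields), restoring the best-validation
parameters. Cross-validation (`mil_crossval()`) partitions *donors*, never
bags, into five groups — 3:1:1 train/validation/test — and trains five
seeded initialisations per fold: 25 models whose out-of-fold predictions
pool into the evaluation. Hyperparameters (gated flag, layer widths, weight
decay, learning rate) are tuned by seeded random search on the fully
labelled count-adequacy task and then frozen for all other tasks so
featureset comparisons stay fair. Seeds control fold assignment, weight
initialisation and sampling; predictions are made in canonical instance
order, so they are exactly invariant to input row permutations.

## Evaluation

ROC and PR curves weight each slide by its tissue count, down-weighting
inadequate biopsies; the weighted ROC-AUC equals the weighted pairwise
Mann–Whitney statistic with half credit for ties, and the tests verify this
to `1e-12` against exhaustive enumeration. Per task, AUCs over the 25 models
are summarised as mean with unbiased standard error (sample SD over models
divided by \(\sqrt{25}\)); across tasks, ROC means pool with
inverse-variance weights (pooled SE \(1/\sqrt{\sum \mathrm{se}^{-2}}\)) and
PR means with the arithmetic mean, whose variances are too small on hard
tasks for inverse-variance weighting to be meaningful. PR curves use
step interpolation (precision held right-constant). Multi-class tasks are
macro-averaged over one-vs-rest AUCs with equal class weights before
pooling. The operating point is the curve's tangency with the maximum
iso-accuracy line under the weighted prevalence, ties broken toward higher
sensitivity. Bootstrap bands resample bags within the test pool (default
five resamples), show the median-AUC curve and the pointwise range, and
redraw degenerate one-class resamples.

## Synthetic data: what it emulates, and what it does not

`synth_slide()` draws tubule-like rings, glomerulus-like capsule rings with
a blob-packed tuft and an empty urinary-space gap, vessel-like thick rings
with a configurable lumen fraction, and nuclei as small dark disks, all
with recorded masks and generative parameters, so that discretised areas
can be checked against closed forms (agreement within 2% for radii of at
least 20 px). `synth_stack()` smooths the ground-truth indicator with a
1 px Gaussian — soft maps, like real network outputs — and adds per-model
noise whose per-instance amplitude follows the requested disagreement,
optionally injecting false-positive blobs visible to only some models.
`synth_bags()` builds bags of Gaussian feature vectors: signal instances
shifted by the effect size along a fixed unit direction, corrupted
instances mimicking the positive signature irrespective of the bag label
(an artefact that resembles a lesion; in a negative bag this is evidence
correlated with the wrong class) and carrying a disagreement proxy
`sigma2` drawn from a distribution with a ten-fold higher mean than clean
instances. Binary labels follow the standard MIL rule; the ordinal mode
assigns three classes by signal count (<7, 7–9, >= 10), mirroring
glomerular adequacy grading.

Default study conditions: 200 bags, 8–16 instances per bag, feature
dimension 10, effect size 3, 20 donors; contamination 0.3 for the
quality-weighting contrast; 400 bags and 25 donors for the ordinal tuning
task. In ordinal mode the total bag size is held constant (background
count = size minus signal count): a softmax-attention pooler observes
*fractions*, not sums, so a constant denominator is what makes the count
identifiable — with variable bag sizes the task is near-chance for this
model class no matter the training.

What passing these tests shows is that the machinery — fusion, weights,
attention, protocol, metrics — behaves as specified under known generative
conditions. What it cannot show is performance on real histology: the
generator has no stain variation, no scanner artefacts, no correlated
instance features, and its corruption model is a stand-in, not a claim
about real artefact morphology.

## Numerical choices and degenerate inputs

* Probabilities are clamped to \([10^{-6}, 1-10^{-6}]\) before log-odds.
* The quality-weight denominator degenerates when all \(s_j^2\) are equal;
  all weights are then 1.
* `attend_weighted` with all-zero \(g\) zeroes every score: attention is
  uniform.
* Empty foreground after the cut yields an empty instance list, not an
  error; components under the minimum area are dropped.
* Crops touching the slide border are clipped and flagged truncated —
  small biopsies keep their truncated tissues.
* Outside-crop blurring (Gaussian, sigma 8 px; the kernel choice is ours)
  is computed before masking so tissue colour cannot bleed back as sharp
  structure; blurring a constant image is the identity.
* "Validation AUC stagnant" is operationalised as no improvement greater
  than \(10^{-4}\) for 40 consecutive epochs.
* Stage seeds derive from the global seed by a stable string hash,
  keeping every pipeline stage independently reproducible; all seeds stay
  below \(2^{31}\).

## Problem sizes

The test-suite and acceptance runs use 160–320 px slides, ensembles of 2–6
models, bags of 30–400, and training runs of at most a few hundred epochs
with early stopping — sizes chosen so a full end-to-end run completes on a
single CPU in minutes while every statistical check retains its power
(e.g. the binomial tolerance on the contamination rate uses over 1,000
instances).

## Worked example

```{r example, eval = FALSE}
bags <- bag_config(n_bags = 200, effect = 3, contamination = 0.3,
                   seed = 21) |>
  synth_bags() |>
  bag_quality_weights()

don <- unique(bags$bags$donor_id)
split <- list(train = bags$bags$bag_id[bags$bags$donor_id %in% don[1:12]],
              val = bags$bags$bag_id[bags$bags$donor_id %in% don[13:16]])
test_ids <- bags$bags$bag_id[bags$bags$donor_id %in% don[17:20]]

fit <- mil_train(bags, mil_config(seed = 1, use_quality_weights = TRUE,
                                  include_g_feature = TRUE), split)
glance(fit)

preds <- mil_predict(fit, bags, test_ids)
roc <- weighted_roc(preds, label, .pred_1)
glance(roc)
autoplot(roc)
```

## Known limitations

* The attention aggregator is ratio-based: counting tasks are solvable
  only insofar as the signal fraction carries the count (see the ordinal
  design note above).
* The max-pooling baseline trains through the selected instance only, the
  standard (high-variance) estimator for that model.
* The student model used for occlusion saliency is a small one-hidden-layer
  regressor on luminance thumbnails; the contract is its attention-weighted
  L2 loss, not the architecture, and depth/width are configurable.
* Probability stacks must arrive co-registered on one grid; resampling
  maps across magnifications is the caller's responsibility.
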