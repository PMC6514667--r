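---
title: "Methods: predicting brain-region connectivity from voxel-level gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting brain-region connectivity from voxel-level gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxconn)
```

## The problem

Brain regions that are anatomically connected tend to have similar gene
expression profiles. `voxconn` operationalises that observation as a
supervised learning problem: given the in-situ-hybridization expression
profiles of one voxel from a *Source* region and one voxel from a *Target*
region, predict the strength of the anatomical projection from Source to
Target.

The data model follows the Allen Mouse Brain Atlas conventions:

- **expression grids** — one volume per gene at a coarse resolution
  (200 µm style), all registered to a common reference space, giving a
  genes × voxels matrix;
- **projection grids** — one volume per viral-tracer injection experiment
  at a fine resolution (100 µm style; exactly 2× the coarse density per
  axis), with the injected (Source) region known per experiment;
- **annotation vectors** — one region ID per voxel at each resolution,
  with 0 for voxels outside any annotated structure, plus a hierarchical
  *structure graph* used to roll fine annotations up to a common level
  (`harmonize_annotation()`).

## From projections to labels: median-then-max

A single injection reports a projection density at every fine voxel. The
connectivity of an ordered pair (Source, Target) is computed in two stages:

1. **median per experiment** over exactly the voxels annotated as the
   Target region (all of them — the projection volume defines a value at
   every voxel, so zeros count). The median is robust to outlier voxels.
   Even-length sets use the mean of the two middle values.
2. **max across experiments** that share the Source. Injection placement
   varies; peripheral placements under-report the projection, so the
   best-placed experiment is taken as representative. A pair with no
   experiments is *absent*, not zero (`aggregate_pair()` on an empty set
   is an error by design).

Aggregated values map to classes through two empirical thresholds,
`t_low = 0.006` and `t_high = 0.1`:

| value                | multiclass    | binary      |
|----------------------|---------------|-------------|
| exactly 0            | 0 unconnected | 0 unconnected |
| (0, 0.006)           | excluded      | excluded    |
| [0.006, 0.1)         | 1 weak        | 1 connected (for value > 0.006) |
| ≥ 0.1                | 2 strong      | 1 connected |

Two boundary conventions are ours, because the interval definitions leave
them open: the value 0.1 itself goes to class 2 (strong treated as
≥ `t_high`; the alternative affects a measure-zero set), and in the binary
task the value 0.006 exactly is excluded (the class is defined by a strict
`> t_low`). "Unconnected" means *exactly* zero after aggregation; there is
no detection floor. Excluded pairs are dropped from datasets rather than
forced into a class — the class definitions jointly do not cover
(0, 0.006).

## From labels to datasets

For every labeled pair, `M` Source voxels and `M` Target voxels are drawn
uniformly (default without replacement; with replacement plus a warning if
the region has fewer than `M` eligible voxels). Voxels whose expression
column is all-zero are ineligible — the same voxels the database layer's
zero filter removes. Each vector is the Source voxel's G-gene profile
concatenated with the Target voxel's (length 2G, source half first). The
default pairing is `index_paired` (M vectors per pair); a full `M²`
`cross_product` is available.

Per-class caps then subsample over-represented classes (the reference
protocol caps at 5000/5000/all for the three-class task), and the pool is
split train/validation/test. The default fractions (0.72, 0.08, 0.20)
reproduce the reference partition 10,499 / 1,167 / 2,917 of a 14,583-vector
dataset; overall sizes follow `round()` on the test and validation
fractions with the remainder to train, and per-class allocation uses
largest-remainder rounding, so the totals are exact and every class is
within one vector of its stratified expectation.

Min–max normalization to [0, 1] is fitted **on the training partition
only** and the same affine map is applied to validation and test, with
out-of-range values clipped; features constant on train map to 0. Fitting
on the full set (`normalize_on = "all"`) exists for strict replication
attempts but leaks test statistics into the scaler.

`split_dataset(..., by_pair = TRUE)` allocates whole region pairs instead
of single vectors. This matters for interpretation: under the default
vector-level split, voxels of the same pair occur on both sides, so test
accuracy partly measures recognising a known pair from a new voxel. The
pair-disjoint option measures generalization to unseen pairs. See the
zero-signal control below.

## The classifier

A multilayer perceptron: dense 64 (sigmoid) → dropout → dense 32 (ReLU) →
dropout → dense 32 (ReLU) → dropout → head. The head is a 3-way softmax
with categorical cross-entropy (multiclass) or a single sigmoid with
binary cross-entropy (binary; decision threshold fixed at 0.5, the ROC
sweeps all thresholds). Training uses Nadam (Nesterov-accelerated Adam)
with learning rate 0.002, β₁ = 0.9, β₂ = 0.999, and a per-update decay
`lr_t = lr / (1 + 0.004·t)` — the common convention for this optimizer
family. Defaults: 200 epochs at batch size 6 (multiclass), 100 epochs at
batch size 32 (binary). There is no early stopping; the validation
partition is monitored, never acted on. Weight initialisation
(Glorot-uniform), shuffling and dropout masks all derive from the config
seed, so training is bit-reproducible.

Numerical notes: softmax is computed with the row-max subtracted;
cross-entropy clamps probabilities at 1e-12; Nadam uses ε = 1e-7; dropout
is *inverted* (activations scaled by 1/(1−p) at train time) so the
evaluation-time forward pass needs no rescaling.

Dropout rates are deliberately exposed: the defaults (0.3, 0.2, 0.2) are
sized for datasets of tens of thousands of vectors. On the synthetic tasks
below — hundreds of training vectors — those rates stall convergence
entirely (the middle connectivity class collapses while a 1-nearest-
neighbour baseline is perfect), so the synthetic studies set them to 0.

Evaluation reports the confusion matrix with **rows = true class,
columns = predicted**, row-normalized percentages, per-class precision
(TP/(TP+FP)), recall (TP/(TP+FN)) and F1, overall accuracy, and for the
binary head a tied-score-aware ROC with trapezoidal AUC. Metrics that are
undefined (a class absent from the test set, or never predicted) are
reported as `NA`, never as 0.

## The synthetic atlas

No public accession accompanies the reference data, and live atlas APIs
are out of scope, so every stage is exercised on a simulated atlas with a
*planted, tunable* expression–connectivity signal.

Each region `r` gets a latent embedding `e_r ~ N(0, I)` in
`latent_dim` dimensions. Its mean expression profile is a fixed linear
readout `baseline + e_r B` (baseline per gene ~ U(2, 6), loadings
~ N(0, 1.5²)); each voxel of the region expresses
`max(0, profile + N(0, noise_sd))`, background voxels are zero. Every
ordered pair (s, t) receives a latent score

`score(s,t) = effect_size · z(s,t) + ε,  ε ~ N(0, 0.3)`

where `z` is the standardized embedding dot product. The
`frac_unconnected` share of pairs with the *lowest* scores becomes exactly
0; the rest map to `0.05 · exp(score)`, a scale chosen so typical values
straddle both labeling thresholds. Coupling the zero set to the same score
— rather than masking pairs independently at random — is what makes the
label a genuine function of expression: with `effect_size = 0` the score
is pure noise, so connectivity is statistically independent of expression
(and the marginal probability of being unconnected is still
`frac_unconnected`); with a large `effect_size`, both which pairs are
unconnected and how strong the others are follow embedding similarity.

Regions are contiguous axis-aligned blocks of the coarse grid — anatomy
realism is irrelevant to the computations under test — and the fine grid
is exactly the coarse grid upsampled 2× per axis, so each coarse voxel
owns 8 fine voxels. Projection volumes fill every fine voxel of each
connected target with `max(0, f_e · value + N(0, proj_noise_sd))`, where
the experiment-level factor `f_e ~ U(1 − jitter, 1]` is multiplicative
and never exceeds 1 — which is precisely why max-over-medians is the
consistent estimator of the planted value, and why, with
`jitter = proj_noise_sd = 0`, the aggregation recovers it exactly (a
property the tests assert elementwise). The generator emulates: spatially
coherent region-level expression, multiple noisy injections per source,
resolution mismatch between modalities, and background voxels. It does
not emulate anisotropic region shapes, within-region expression
gradients, secondary (multi-region) injections, or spatially structured
measurement noise — so passing tests certify the computations, not
performance on real atlas data.

Defaults (8 regions, 16×12×14 coarse grid, 50 genes, latent dimension 4,
`effect_size` 5, `noise_sd` 0.5, 3 injections per source,
`frac_unconnected` 0.4, `jitter` 0.3, `proj_noise_sd` 0.005) are the
package's study conditions: small enough that the full pipeline runs in
seconds, large enough that every class is populated and the planted
signal dominates the noise.

## The two designed experiments

**Parameter recovery (binary).** Five seeds of the default atlas,
`M = 10`, all pairs kept, vector-level split, 100 epochs at batch size
32. Mean test accuracy and AUC measure whether the pipeline recovers the
planted signal end to end. The **zero-signal control** repeats this with
`effect_size = 0` but a *pair-disjoint* split: under a vector-level split
a network can label held-out vectors by recognising their region pair
(the labels are fixed per pair), so chance level is the wrong null there;
with pair-disjoint evaluation, no information means accuracy at the
majority rate and AUC near 0.5. Because the test vectors cluster by pair
(~12 effective units), the control's AUC wobbles more than its nominal
vector count suggests.

**Well-separated strata (multiclass).** A 12-region atlas with
`noise_sd = 0.3`; pairs whose value falls within roughly a factor 2 of
either threshold are dropped, so the three strata carry a margin in
connectivity — and therefore in expression — space; classes are balanced
by the per-class caps (the same mechanism the reference protocol uses);
`M = 25`; 100 epochs at batch size 6, dropout off. Macro-F1 counts a
collapsed class as 0 rather than dropping it. The companion analysis
driver keeps the full unfiltered pair set as the honest harder task: its
confusion matrix shows the weak class absorbing the boundary-ambiguous
pairs, the expected behaviour when strata are *not* separated.

Problem sizes throughout (grids of a few thousand voxels, tens of
regions, ≤ ~1500 vectors, ≤ 200 epochs) are the package's chosen study
scale; every quantity in `scripts/acceptance.R` is recomputed from
scratch at that scale on each run.

## Storage

Processed atlases persist in an SQLite database with the four tables
`voxID2Annotation` (voxel → structure), `voxID2GenExpr` (zero-filtered
expression triples; absent rows read back as 0), `injection2regionID`
(injection → source region) and `injection2target` (injection, per-target
median, target ID), plus a small `meta` table (schema version, dims,
resolution, gene IDs) so `load_database()` reconstructs the exact
in-memory objects. Raw expression volumes are float32 little-endian with
a JSON sidecar recording dims and the x-fastest linearization order (the
reference format names neither); projection volumes are minimal NRRD0004
(raw encoding, little-endian float); voxel IDs are 0-based flat indices.
Readers trust header dimensions and verify payload sizes, and every
reader/writer round-trips bit-exactly on its own output.

## Known limitations

- The planted generative model is linear-Gaussian with a log-linear
  connectivity link; real expression–connectivity structure is richer.
- The multiplicative-jitter injection model makes max-over-medians exactly
  the right estimator; real peripheral injections also displace projections
  spatially, which is not simulated.
- Reference-scale performance numbers require the real atlas data and are
  out of scope; nothing here should be read as reproducing them.
- The optional full-set normalization mode leaks test statistics by
  construction; it exists only for replication comparisons.
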