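---
title: "Progressive multitask stacked forests: model, diagnostics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive multitask stacked forests: model, diagnostics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chemical toxicity panels are sparse: each endpoint is measured on its own
chemical collection, collections barely overlap, and many endpoints are
heavily imbalanced. Conventional multitask learners assume a common design
matrix across tasks, which these data do not provide. The approach
implemented here sidesteps that assumption by exchanging information
between tasks through *model outputs* rather than shared samples: any
task's model can score any chemical, so a panel of per-task models defines
a dense, shared "biological" feature space even when the underlying
assay data are disjoint.

## The model

Let $m$ be the fingerprint length (1024-bit ECFP6 by default) and $T$ the
number of tasks. Training proceeds in layers:

1. **Layer 1.** For each task $t$, a probability random forest is trained
   on that task's training chemicals using the raw fingerprint
   $x \in \{0,1\}^m$. This layer is exactly the single-task baseline.
2. **Layer $k \ge 2$.** Every chemical of every task is scored by all $T$
   forests of layer $k-1$, giving a score vector $s \in [0,1]^T$. Each
   task's layer-$k$ forest is trained on the concatenation $[x, s]$
   (width $m + T$) of the *original* fingerprint with the
   *immediately previous* layer's scores — scores do not accumulate
   across layers.
3. **Selection.** Each layer's per-task AUC on the validation split is
   averaged; layers are added until a new layer fails to strictly improve
   the best mean validation AUC (or a configurable cap is reached). The
   reported model uses the argmax layer, so the selected layer can never
   be worse than the single-task baseline on the validation criterion.

Forests use 500 trees, `mtry = floor(log2(p))` where $p$ is the width of
the matrix actually being fit (so stacked layers use `log2(m + T)`), and a
fixed forest seed of 8; all forests run single-threaded so results are
bit-reproducible. Each task is split 70/10/20 into
train/validation/test. The split is stratified by label — with tasks at or
below 10% positives, an unstratified 10% validation slice would frequently
lose a class entirely and leave the selection criterion undefined.

Two details are deliberate:

* **A task's own score is included** in its stacked input. Excluding it is
  supported (`includeOwnScore = FALSE`) for ablation, but inclusion is the
  default because the own-task score is a legitimate compressed summary of
  the previous layer's fit.
* **Score features are direct predictions** of the previous layer's
  forests, including on chemicals those forests saw in training. No
  out-of-fold scheme is used; the score columns are therefore optimistic
  for training chemicals, which the next layer's validation-based
  selection guards against. This is the simplest scheme consistent with
  layer-wise stacking; an out-of-fold variant would roughly double
  training cost per layer.

Tasks whose validation split holds a single class get an undefined AUC and
are excluded from the layer mean with a warning; imputing a value (0.5 or
otherwise) would bias layer selection for no benefit.

## Chemical-space diagnostics

Two datasets are compared subset-by-subset (a "subset" being one named
chemical list with fingerprints):

* **Common-chemical percentage**: for each subset pair,
  $100 \cdot |A \cap B| / |A \cup B|$ over chemical identifiers; the
  maximum over pairs is reported. The union denominator means a small
  panel fully contained in a large one does not score 100 unless the
  sets coincide per subset.
* **Average Tanimoto similarity**: for each subset pair, the mean
  Tanimoto similarity over all cross pairs of chemicals; the unweighted
  mean over subset pairs is reported (times 100). Chemicals present in
  both subsets contribute their self-similarity of 1. A pooled variant
  (`pooled = TRUE`) weights subset pairs by their cross-pair counts
  instead; the unweighted form is the default because the quantity is
  defined per subset pair.
* **Label correlation bins**: for every unordered task pair, the Pearson
  correlation of binary labels over chemicals labeled in both tasks,
  binned by $|r|$ at 0.3 / 0.5 / 0.7. Pairs with fewer than `minShared`
  (default 3) shared chemicals, or zero label variance on the shared
  chemicals, are uncategorized — two shared points always give $|r| = 1$
  and are uninformative, hence the floor of 3. Correlations are computed
  on binary labels, not on the underlying continuous endpoint values.
* **PCA**: mean-centered, unscaled principal components of the binary
  fingerprint matrix, the standard projection for fingerprint spaces
  (bits share a scale, so variance scaling would only inflate rare bits).

## Fingerprints and import

ECFP6 ("diameter 6", i.e. circular radius 3) fingerprints and MACCS keys
are computed through Open Babel. Open Babel emits the ECFP6 hash at 4096
bits; the package folds it by OR to the requested length (1024 by
default), the standard treatment of hashed fingerprints. Import
conservatively rejects rather than repairs: multi-fragment structures
(salts, mixtures) are rejected instead of desalted — no desalting protocol
is assumed — and duplicates are detected on canonical structures, not raw
SMILES text, keeping the first occurrence. Every rejection carries a
reason and can be written to a report file. Endpoint binarization follows
the printed threshold operators exactly: a rule like "BMD10 at or below
1 mM" is inclusive, a rule like "score above 2.24" is strict, and missing
endpoint values become missing labels that exclude a chemical from that
task only.

## EZ Metric

The embryonic zebrafish metric is the weighted sum of binary endpoint
calls (4 endpoints at 24 hpf, 17 at 120 hpf) under nonnegative,
user-supplied weights; `inst/extdata/ez_weights_uniform.yaml` ships a
uniform placeholder clearly marked as such. Missing calls are skipped by
default — an unmeasured endpoint contributes nothing — mirroring how
panels with unavailable endpoints are scored in practice; a strict mode
errors instead. Comparing predicted against experimental calls reports
the per-chemical score pairs, their Pearson correlation, and the bias
(mean predicted minus experimental), whose sign says whether the model
over- or under-calls overall toxicity.

## Downstream augmentation and feature selection

A fitted panel model turns any fingerprint matrix into $T$ binary calls
(probability threshold 0.5 by default; the threshold is a parameter, not
a claim about calibration). Appended to the fingerprint these give a
$m + T$ design matrix for external endpoints. Because the call columns
can be redundant, a floating backward search
(`sbfsConditional`) filters them: starting from all candidates, the
removal that maximizes k-fold cross-validated AUC is applied; after each
removal, any previously removed candidate is re-admitted while doing so
strictly improves the current CV AUC; the best subset encountered is
returned, with ties broken toward the smaller set and then
lexicographically. Fold assignment is fixed once per search so subsets
are compared on identical folds, and subset evaluations are memoized.
The search stops after `patience` (default 2) consecutive removal rounds
that fail to improve the best CV AUC — continuing an elimination that has
stopped improving mostly re-scores noise, and the best-seen return rule
makes early stopping safe: the result can never score below the full
candidate set. Selection runs on training rows only; the held-out rows of
each evaluation run never reach the search or the model fit.

`repeatedEvaluation` repeats stratified 80/20 splits (100 by default),
optionally augmenting and selecting per run, and reports the mean and
variance of test AUC plus per-column selection frequencies. Per-run seeds
derive from the master seed by the fixed affine map
`(seed * 1009 + run) mod (2^31 - 1)`, so runs are independent but the
experiment is reproducible end to end.

## The synthetic benchmark generator

The generator emulates the structure that makes multitask panels hard:

* **Pools.** Chemicals live in pools; a pool has a random prototype bit
  pattern (density 0.15) and each chemical flips each prototype bit with
  probability 0.1. Disjoint pools occupy distinct bit-space regions, so
  between-pool Tanimoto similarity is low while within-pool similarity is
  high. Tasks drawn from one pool share that pool's chemical list —
  mirroring real panels where many endpoints are assayed on one chemical
  collection — while tasks from different pools share nothing.
* **Labels.** Each chemical's latent projection is $z = Px$ for a fixed
  sparse random matrix $P$ (about 32 nonzero weights per latent
  dimension). Task $t$ uses the unit-normalized weight vector
  $w_t = \rho\, w_{\text{shared}} + (1-\rho)\, w_t^{\text{private}}$, and
  labels are $\mathbb{1}[w_t \cdot z + \varepsilon > \tau_t]$, with
  Gaussian margin noise at 10% of the within-task margin spread and
  $\tau_t$ set by the margin quantile that hits the target positive
  fraction (a quantile rather than a closed form, so calibration is
  robust to any noise setting). Labels then flip independently with
  probability `labelNoise`. Deriving labels from a latent projection
  rather than raw bits is what lets related tasks carry mutual signal
  even when their chemicals are disjoint in bit space.
* **Relatedness.** $\rho = 1$ makes all tasks share one labeling rule;
  $\rho = 0$ makes them independent; class imbalance down to a few
  percent positives is a per-task target fraction.

The canonical transfer benchmark (`transferBenchmarkConfig`) uses 8 tasks
of 400 chemicals from 4 disjoint pools, 1024-bit fingerprints, latent
dimension 16, label noise 0.1 and balanced classes. At $\rho = 0.9$ the
stacked model's mean test AUC should clearly exceed the single-task
baseline; at $\rho = 0$ the difference should vanish — the null control
that the stacking mechanism does not manufacture improvement from its own
machinery.

What the generator does *not* emulate: real structure–activity
relationships (fingerprint bits are noise around prototypes, not
chemistry), assay noise structure, inter-endpoint biological hierarchies,
or realistic chemical-space geometry. Passing benchmarks therefore
demonstrate that the algorithm recovers cross-task signal of the stated
form and strength, not that any particular real panel will gain the same
amount.

## Problem sizes and numerical choices

The test suite exercises the pipelines at these scales, chosen to make
the statistical assertions stable under the fixed seeds while keeping a
full run comfortable on one core: transfer and null benchmarks at the
canonical 8 x 400 configuration over 10 seeds with the layer cap at 4
(the benchmark typically selects layer 2–4); layer-1 equivalence on 5
tasks of 150 chemicals with 256-bit fingerprints; floating selection on
10 candidates (1 perfectly predictive, 9 noise) at $n = 300$ with
tenfold CV and 100-tree forests; the downstream comparison on 400
chemicals with 16 call columns (3 informative) over 20 repeated splits.
Oracle equivalences (rank-based AUC versus exhaustive pair enumeration;
set-arithmetic chemical-space metrics) are checked to $10^{-12}$.

Other numerical conventions: Tanimoto similarity of two all-zero
fingerprints is 0; AUC uses midranks, so ties receive exactly half
credit; layer selection requires *strict* improvement of the mean
validation AUC, so plateaus terminate training and a tie never adds a
layer; probability thresholds compare with `>=`.

## Known limitations

* Score features for training chemicals are in-sample predictions (see
  above); panels with very small tasks may overstate layer-2 validation
  gains, though selection still cannot pick a layer that fails on
  validation.
* The stacked model is as deterministic as the forest library; identical
  seeds reproduce identical models on one platform, but forests are not
  guaranteed bit-stable across BLAS/compiler variations.
* The EZ Metric module consumes binary calls; it does not fit
  dose–response curves, and weight values are user input.
* Mixture handling is rejection, not desalting; panels rich in salt forms
  will see higher reject rates than toolkit pipelines that strip
  counterions.
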