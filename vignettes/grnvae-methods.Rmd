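---
title: "Methods: prior-guided variational inference of TF activity and GRNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prior-guided variational inference of TF activity and GRNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`grnvae` treats per-cell transcription-factor (TF) activity as a latent,
non-negative quantity and the gene regulatory network (GRN) as the final
linear layer of a generative model.  For a cell's (log-normalized)
expression vector $x \in \mathbb{R}^G$:

$$
(\mu, \sigma) = q_\phi(z \mid x), \qquad
z = \mu + \sigma \odot \varepsilon, \; \varepsilon \sim \mathcal N(0, I),
$$
$$
e^{\mathrm{dec}} = p_\theta(e \mid z) \ \ (\text{ReLU output}), \qquad
\hat e = (1 - \alpha)\, e^{\mathrm{ULM}} + \alpha\, e^{\mathrm{dec}}, \qquad
\hat x = \hat e \, W .
$$

$W$ is a $K \times G$ real matrix: sign encodes activation vs repression,
magnitude encodes strength.  Because the last layer is linear and bias-free,
$W$ is directly interpretable as a weighted GRN, and the ReLU TF head makes
every reported activity non-negative ("how strongly is this TF acting in
this cell", on a relative scale).

The training objective (minimization convention) is

$$
\mathcal L \;=\;
\underbrace{\tfrac1B \sum_i \lVert x_i - \hat x_i \rVert^2}_{\text{reconstruction}}
\;+\;
\underbrace{\tfrac1B \sum_i \tfrac12 \sum_d
  (\mu_{id}^2 + \sigma_{id}^2 - 1 - \log \sigma_{id}^2)}_{\text{KL}}
\;+\;
\underbrace{\gamma(t) \sum_{k,j} \lvert w_{kj} \rvert}_{\text{GRN sparsity}} .
$$

A Gaussian reconstruction term (squared error) is used because inputs are
expected to be log-normalized; a count likelihood (negative binomial) is
deliberately out of scope, and the synthetic generator matches this
assumption (see below).

## The three schedules

Training moves from prior-driven to data-driven inference through three
scheduled mechanisms, all advanced once per epoch $t = 1,\dots,T$:

1. **Activity blending** $\alpha$: starts at `alpha_start` (default 0),
   increases by `delta_alpha` (default 0.02) per epoch, saturates at
   `alpha_max` (default 0.9).  Early on, activities are the ULM estimates
   (stable, prior-anchored); late in training the decoder dominates, but a
   $1 - \alpha_{\max} = 10\%$ ULM share is retained permanently as an
   anchor against representation drift.
2. **Prior mask** $m(t) = 1 / (1 + \exp((t - T/2)/(T/20)))$: after each
   optimizer epoch, $W \leftarrow m(t) W_{\mathrm{prior}} + (1 - m(t)) W$.
   The mask decays from $\approx 1$ ($m(0) = 1/(1+e^{-10})$) to
   $\approx 0$ ($m(T) = 1/(1+e^{10})$), crossing $1/2$ exactly at $T/2$
   with a transition width of $T/20$ epochs, so the prior is enforced in
   the first half of training and fully released in the second.  A
   *rising* variant of this logistic is available behind the
   `mask_increasing` flag: the rising curve would enforce the prior ever
   more strongly and never let learned weights replace it, which
   contradicts the intended prior-to-data transition, so the decaying
   orientation is the default.
3. **Sparsity ramp** $\gamma(t) = \gamma_{\max}\, t / T$ (default
   $\gamma_{\max} = 10^{-3}$): ramping *up* from zero lets early training
   follow the prior before L1 shrinkage starts pruning weak edges; a
   constant or decaying $\gamma$ would penalize the prior initialization
   itself.

$W$ is initialized to the signed prior (ternary $\pm 1$, binary $+1$,
magnitude 1), so epoch 0 reproduces prior-only regulon scoring.

## ULM activities

The prior-driven estimate for TF $k$ in a cell is the **slope
t-statistic** of the univariate regression of the cell's expression vector
(across genes) on the TF's prior weight vector — the classic univariate
linear model (ULM) regulon score.  In closed form, with centered regressor
$w$ and profile $x$ over $G$ genes:

$$
b = \frac{\sum_j w_j x_j}{\sum_j w_j^2}, \qquad
t = \frac{b}{\sqrt{\mathrm{RSS} / ((G-2) \sum_j w_j^2)}} .
$$

Raw t-statistics can be negative; they are clipped at zero wherever the
non-negative activity convention applies (blending, reported activities)
and retained unclipped internally (`ulm_activities(..., nonnegative =
FALSE)`).  Degenerate regressors (constant prior column) score 0;
regressions with numerically zero residual variance are floored to keep the
statistic finite.  Because the ULM scores do not depend on model
parameters, they are computed once per cell before training and indexed per
minibatch.

## Optimization and numerical choices

* **Optimizer**: Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning rate
  $10^{-3}$, minibatch 128, with a plateau scheduler that halves the
  learning rate after 10 epochs without improvement of validation total
  loss.  Cells are split 85/15 into training and validation by a seeded
  uniform shuffle (validation size clamped to $[1, n-1]$).
* **Architecture defaults**: encoder 128-unit hidden layer, latent
  dimension 32, decoder 64-unit hidden layer before the TF head.  The
  encoder admits 1–3 and the decoder 1–2 hidden layers; the GRN layer is
  always present and is not counted as a decoder layer.
* **Log-variance clamp**: the encoder's log-variance head is clamped to
  $[-12, 12]$ (with pass-through gradient inside the interval) to keep
  $\sigma = \exp(\tfrac12 \log \sigma^2)$ finite during early training.
* **Schedule stepping**: $\alpha$, $m$ and $\gamma$ advance per *epoch*,
  not per minibatch, so the schedule length is controlled by `epochs`
  alone and is independent of dataset size; the $W$ blend is likewise
  applied once per epoch, after the optimizer steps.
* **Determinism**: one user-facing seed derives separate streams for the
  split, weight initialization, minibatch shuffling, latent draws, the
  simulator's noise/dropout, and clustering.  With single-threaded
  numerics, two runs of the full pipeline are byte-for-byte identical
  (this is asserted in the test suite).
* **Duplicate prior edges** collapse by sign majority, ties resolving to
  $+1$ (activation), a deterministic and documented rule.
* **Joint filtering** runs genes → cells → TFs (a gene needs expression in
  ≥ 10 cells *and* ≥ 1 prior TF; a cell needs ≥ 3 retained genes; a TF
  needs ≥ 10 retained targets), then performs exactly one re-check pass so
  genes orphaned by TF removal are dropped without an unbounded
  fixed-point loop.  "Expressed" means strictly positive, which is correct
  for both counts and log-normalized values.  The cell threshold of three
  genes is unusually permissive and is therefore exposed as a parameter.
  Standard upstream preprocessing (mitochondrial filtering, HVG selection,
  normalization) is left to dedicated tooling; `lognorm_cpm()` is provided
  as a convenience only.

## Per-cluster fine-tuning

`finetune_clusters()` copies the global parameters per cluster and
continues training on that cluster's cells at
`learning_rate * finetune_lr_scale` (default scale 0.1 — a guard against
catastrophic forgetting of the global solution), with $\alpha$ held at
$\alpha_{\max}$, the mask frozen at its terminal value $m(T) \approx 0$
and $\gamma$ at $\gamma_{\max}$, so the refinement is purely data-driven.
Nothing is frozen structurally.  Because Adam's effective step is bounded
by the learning rate, cluster-specific rewiring of $W$ accumulates slowly
at the reduced rate; the default of 200 fine-tuning epochs suits mild
specialization, and several hundred epochs are appropriate when cluster
networks are expected to differ substantially (the cluster-recovery test
uses 600).  Clusters smaller than 20 cells are skipped with a warning —
below that, the within-cluster validation split becomes meaningless.

# Downstream analytics

* **Scaled GRNs**: each TF's outgoing weights min–max scaled to $[0,1]$
  (constant rows map to 0); used for cross-TF and cross-condition
  comparison.
* **Differential TF activity**: two-sided Wilcoxon rank-sum of each TF's
  activities in a group vs all other cells, Benjamini–Hochberg adjusted
  across TFs *within* each group (BH is the field default where the
  adjustment is otherwise unspecified); effect size
  $\log_2((\bar a_{\mathrm{in}} + \epsilon)/(\bar a_{\mathrm{out}} +
  \epsilon))$ with $\epsilon = 10^{-9}$, since ReLU activities can be
  exactly zero.  The LFC is computed on raw (unscaled) activities: scaling
  is per-TF and would distort cross-group ratios within a TF.  Retained
  TFs ($p_{\mathrm{adj}} < 0.05$) are ranked by descending LFC.
* **TF–TF co-regulation**: cosine similarity between rows of $W$,
  thresholded at 0.8 by default ("high similarity" is not otherwise
  quantified; the threshold is a parameter).
* **GRN similarity across cell types**: absolute weights, per-TF min–max
  normalization, flattening, pairwise Pearson correlation, and
  average-linkage hierarchical clustering on $1 - r$ (average linkage is
  the conventional choice where the linkage is unspecified).
* **Ranked targets**: the top 1% of genes per TF by scaled weight are
  exported for use with external enrichment tools; enrichment itself is
  out of scope.

# Evaluation utilities

* **Clustering benchmark**: Leiden on a 15-nearest-neighbour Euclidean
  graph of the raw activities, swept over resolutions 0.2–3.0; predicted
  clusters receive their modal ground-truth label (ties broken
  lexicographically), then ARI (permutation-adjusted Rand), NMI
  (arithmetic normalization) and macro-F1 over the true label set are
  computed.  The additional "AUC" is a macro one-vs-rest AUROC treating
  the assigned-label indicator as the score; it is a documented
  construction of this package (the metric has no standard definition in
  this setting) and should not be compared against published AUC values.
* **GRN recovery**: $|W|$ scored against a binary ground truth over the
  intersection of TF *and* gene sets (gene intersection alone would leave
  scores undefined under TF mismatch), with midrank tie handling; AUPRC is
  average precision over the distinct-threshold sweep.  Both equal
  exhaustive threshold enumeration exactly (property-tested on random
  instances).
* **Dropout robustness**: Bernoulli masking
  $X'_{ij} = X_{ij}\,\mathbb 1(U_{ij} > p)$ at $p \in \{0.1, 0.3\}$,
  re-running inference and clustering on the masked matrix.
* **Stratified sketching**: Leiden pseudo-clusters on a 20-PC reduction
  (resolution 1.0), then each cluster's cells are dealt across the
  requested subsets, guaranteeing proportional representation within one
  cell.  The seeded uniform within-cluster split is a deliberate stand-in
  for geometric sketching: the property relied upon downstream is
  proportional coverage, which the uniform split satisfies exactly, and a
  custom backend can be plugged in through the `clusters` argument.
* **Knockdown evaluation**: condition means compared as
  $\log_2((\bar a_{\mathrm{kd}} + \epsilon)/(\bar a_{\mathrm{ctrl}} +
  \epsilon))$ plus a two-sided rank-sum test; `knockdown_screen()` adds BH
  adjustment across TFs.

# The synthetic generator

`simulate_grn_dataset()` produces the controlled regime every training and
evaluation path is tested on: a signed truth network (each TF regulating
`edges_per_tf` genes, log-normal magnitudes, a configurable repressor
fraction), cluster-structured activities (Gamma-distributed, mean 5 where
a TF is "on" in its assigned cluster, 0.5 elsewhere — Gamma keeps them
non-negative, matching the ReLU convention), expression
$A\,W_{\mathrm{truth}}$ plus Gaussian noise (sd 0.5) clipped at zero,
optional Bernoulli dropout, and an exported prior whose edges can be
partially replaced by random false edges (`prior_corruption`) or rewired
per cluster (`cluster_rewire`).  Knockdowns multiply one TF's activity by
a factor and regenerate expression *with the identical noise stream*, so
the perturbation is the only difference between conditions.

Gaussian noise plus clipping — rather than negative-binomial counts — is a
deliberate match to the model's Gaussian reconstruction term: recovery
tests then probe the inference machinery, not likelihood mismatch.
Consequently, passing tests demonstrate correct joint inference of
activities and weights under the model's own assumptions; they do not
demonstrate robustness to count overdispersion, library-size variation,
batch effects, ambient RNA or doublets, which real data exhibit and which
upstream tooling must handle.  Default sizes (500 cells × 200 genes × 15
TFs in 3 clusters) keep a full fit under a few seconds; the heavier
recovery checks use 1000 cells × 400 genes × 25 TFs (150 epochs) and 600
cells with two 50%-rewired cluster networks, sizes at which recovery
margins are comfortable and a complete run stays in the tens of seconds.

# Known limitations

* Performance depends on prior quality; with heavily corrupted priors the
  learned network degrades gracefully (tested at 30% corruption) but is
  not immune to systematically biased priors.
* The Gaussian reconstruction restricts inputs to log-normalized (or
  otherwise variance-stabilized) expression.
* TF activities are relative, per-dataset quantities; they are not
  comparable across independently trained models without calibration.
* The kNN/Leiden utilities use dense distance matrices, intended for
  desk-scale datasets (up to a few thousand cells), not atlas-scale
  inputs.
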