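---
title: "Methods: fused random-walk and graph-convolutional embeddings for disease-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused random-walk and graph-convolutional embeddings for disease-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeprw)
```

## The problem and the model

Disease-gene prioritization asks which genes, out of a large candidate set,
are associated with a disease. The guilt-by-association premise is that
disease genes cluster in functional interaction networks: a gene wired into
a neighbourhood of known disease genes is a better candidate than an
isolated one. `deeprw` operationalizes this with two node representations
learned from a weighted undirected gene network and a per-gene feature
table, fused and classified by a small feed-forward network.

**Network.** `build_network()` constructs `G = (V, E)` from a tab-separated
edge list. Genes with no positive-weight incident edge are removed (the
model has nothing to propagate for them), reciprocal duplicates collapse,
and conflicting duplicate weights are an error rather than silently
averaged. Node order is fixed once, lexicographically; every matrix,
embedding and prediction downstream uses that order, which is what makes
runs bit-reproducible. Edge weights (probabilistic functional-association
scores) are used exactly as given; the package never rescales them.

**DeepWalk branch.** `generate_walks()` samples plain first-order truncated
walks — no restarts, no in-out bias — where the step distribution is
proportional to edge weight (`transition_distribution()`). `train_skipgram()`
fits skip-gram vectors on the corpus. The stated training objective is the
windowed conditional likelihood
\(-\sum_{j=1}^{W}\log P(v_{c_j}\mid v_i)\); the trainer estimates it by
negative sampling (5 negatives, unigram^0.75 noise), which is the standard
estimator of that loss, while `skipgram_loss()` keeps the exact full-softmax
objective available as a probe. The tests verify on a planted two-community
graph that training lowers the probe loss and separates the communities in
cosine similarity.

**GCN branch.** `normalize_adjacency()` builds
\(S = D'^{-1/2} (A + I) D'^{-1/2}\); each `gcn_layer()` computes
\(\mathrm{LeakyReLU}(S X W)\) with negative slope 0.2, and the last layer
keeps its activation. The graph Laplacian \(L = D - A\) is exposed
(`laplacian()`) as a standard view of the network, but the encoder's
propagation operator is \(S\), not \(L\). Note that because the self-loop in
\(A + I\) has weight exactly 1, \(S\) is *not* invariant to rescaling all
edge weights — multiplying weights by 10 shifts mass from the self-loop to
the neighbours. That is a property of the formulas as stated, and the test
suite asserts it rather than pretending scale-invariance.

**Fusion and classifier.** `fuse()` concatenates the two per-node vectors.
The head is affine → batch normalization → leaky ReLU for each hidden layer
and a 2-way softmax output; the loss is binary cross-entropy with
probabilities clipped at `1e-7`. GCN and head are trained jointly under this
loss (the encoder has no other supervision signal), while the deep-walk
embedding is trained separately on the graph alone and enters frozen — it
does not see labels, so it can be computed once per dataset and shared
across cross-validation folds without leakage.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `window` | 10 | skip-gram window half-width (protocol value) |
| `skipgram_iterations` | 10 | passes over the walk corpus (protocol value) |
| `walks_per_node`, `walk_length` | 10, 40 | corpus shape; common DeepWalk practice, unstated in the protocol |
| `embedding_dim` | 64 | deep-walk vector size (unstated; standard) |
| `gcn_layers` | 3 | encoder depth; 2 and 4 supported for the depth ablation |
| `gcn_hidden` | 64 | width of each GCN layer (unstated; standard) |
| `dnn_widths` | 64, 32 | hidden widths of the head; output is always 2-way |
| `max_epochs`, `patience` | 200, 50 | see "early stopping" below |
| `learning_rate` | 1e-3 | Adam with default moments |
| `batch_size` | 32 | 0 = full batch |
| `validation_fraction` | 0.1 | stratified hold-out for early stopping |
| `k`, `repeats` | 10, 10 | cross-validation design (protocol values) |
| `restart_prob` | 0.5 | RWR baseline restart probability (unstated; midpoint) |

"Trained 50 epochs" alongside "stop if no improvement for 50 epochs" is
contradictory as written — the early stop could never fire within 50
epochs. The default here resolves this as `max_epochs = 200` with
`patience = 50` on validation loss; setting `max_epochs = 50` restores the
strict printed protocol (early stopping then inert). Both knobs are
config-exposed.

## Numerical choices

* **Initialization.** Glorot-uniform for all weight matrices, zero biases,
  unit batch-norm scale; all draws from seeded generators. Skip-gram input
  vectors start at U(-0.5/dim, 0.5/dim), output vectors at zero, as in
  classical word2vec.
* **Batch normalization** sits between the affine transform and the
  activation. Training mode uses batch statistics (biased variance) and
  updates running statistics with momentum 0.1; inference mode uses the
  running statistics, so repeated predictions are identical.
* **Early stopping** keeps a deep copy of the parameters and batch-norm
  state at the best validation loss and returns exactly that checkpoint.
  `patience = 0` stops at the first non-improving epoch.
* **Ties and clipping.** AUROC uses the rank (Mann–Whitney) formulation
  with half-credit ties; AUPR is the uninterpolated step curve, with tied
  scores collapsed into one threshold group; cross-entropy probabilities
  are clipped to `[1e-7, 1 - 1e-7]`.
* **RWR** iterates `p ← (1-r) Pᵀ p + r e` to an L1 residual below `1e-10`;
  the result is a probability distribution (conservation is asserted).
* **Determinism.** Walk generation and training use seeded single-threaded
  code end to end (the skip-gram inner loop is C++ with its own mt19937
  stream and no std::distribution types, so it is reproducible across
  builds). Multi-threaded training would break bit-reproducibility; none is
  used. Cross-validation derives one seed per (repeat, fold) from the
  master seed.
* **Degenerate inputs.** Empty edge lists, conflicting duplicate weights,
  self-edges, single-class label sets, nodes missing from the walk corpus,
  unknown nodes at prediction time, and zero row sums in the normalized
  adjacency all raise immediate errors rather than propagating NaNs.

## The synthetic generator: what it emulates, what it does not

`simulate_network()` draws a planted-partition graph: same-class gene pairs
connect with probability `p_in`, cross-class pairs with `p_out`, weights
uniform on (0, 1]. This mirrors the guilt-by-association structure the
method assumes — disease genes preferentially interconnected — with the
network signal (`p_in - p_out`) and the feature signal (`feature_effect`,
class separation per feature in units of `noise_sd`) exposed independently,
so the `withoutGCN` / `withoutDeepWalk` ablations are distinguishable.
`simulate_features()` draws feature `j` of gene `i` from
\(N(\delta\, z_i s_j,\ \sigma^2)\) with a fixed random sign `s_j` per
feature. Genes left isolated by the edge draw are re-wired to one random
same-class partner so the no-isolated-node invariant holds.

Defaults are 142 positives and 142 negatives (the study's design size),
`p_in = 0.10`, `p_out = 0.02`, `feature_effect = 1.5`, `noise_sd = 1`, 30
features — a clear but not extreme signal at which the full model should
essentially solve the task.

What passing tests on this generator do **not** show: real functional
networks have heavy-tailed degree distributions, weight calibration
artifacts, and correlated features; real disease-gene label sets are noisy
and the negative class is a sample of unlabelled genes, not verified
non-disease genes. Absolute metric values on the synthetic design therefore
say nothing about absolute performance on curated data; the tests assert
*relative* and *structural* properties (chance level under permuted labels,
monotonicity in signal strength, ablation ordering, over-smoothing with
depth) that are meaningful under the model's own assumptions.

## Design choices where the design was open

* **Fusion is concatenation** — the simplest operator consistent with two
  parallel branches feeding one classifier; it preserves each branch's
  information and lets the first affine layer learn the mixing.
* **The GCN is supervised end-to-end through the classifier loss**; no
  separate encoder objective is stated anywhere, and joint training is the
  standard reading of an encoder feeding a prediction head. The deep-walk
  branch, by contrast, has its own unsupervised objective and is frozen.
* **Stratified folds.** With 142 + 142 labels, unstratified 10-folds can
  produce class-skewed test sets; stratification protects the 50/50 design.
  Per-class remainders are rotated across folds so overall fold sizes also
  differ by at most one.
* **Negatives are fixed per dataset** (drawn once by the generator, held
  constant across repeats); re-sampling negatives per repeat would conflate
  sampling noise with method variance.
* **Null calibration re-permutes labels per repeat.** A single fixed
  permutation retains its chance alignment with the planted communities
  across all repeats (its expected AUROC is not 0.5 conditional on the
  permutation), so the null experiment draws a fresh permutation for each
  repeat and averages; only then does the mean concentrate at 0.5.
* **RWR test-gene score** is the stationary proximity to the training-fold
  positives, with restart probability 0.5 by default (config-exposed).

## Problem sizes used by the test suite

The heavy end-to-end tests run the full pipeline at the generator's default
142 + 142 design with full-batch Adam (`learning_rate = 5e-3`), GCN/head
widths of 32/16, 32-dimensional deep-walk vectors and 30–80 epoch budgets:
signal recovery and the ablation ordering use 10-fold cross-validation over
5 generator seeds; the null calibration uses 10 independently permuted
single-repeat 10-fold passes per method. Unit-level properties (oracle
equivalence, gradient checks, walk statistics) use graphs of 6–30 nodes.
These sizes are the package's own choices for routine verification; all of
them scale up through the configuration objects without code changes.

## Known limitations

* The model is transductive: training and prediction operate on one fixed
  network; scoring a gene absent from the network requires rebuilding it.
* The skip-gram trainer is single-threaded by design (reproducibility over
  speed); very large corpora would benefit from the usual multi-worker
  word2vec at the cost of bit-identical runs.
* Batch normalization with very small batches (or tiny validation splits)
  is noisy; for a few hundred labelled genes, full-batch training
  (`batch_size = 0`) is both faster and more stable here.
* The kernelized Bayesian matrix factorization and random-forest baselines
  of the original comparison are out of scope; RWR is the in-package
  baseline, and a random forest can be run externally on the same folds via
  `stratified_kfold()`.
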