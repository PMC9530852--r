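# deeprw

Network-based prioritization of disease-associated genes, applied originally
to non-small cell lung cancer (NSCLC). The premise is guilt by association:
genes that interact with known disease genes are themselves more likely to
be disease-associated, so a weighted gene-interaction network (HumanNet-style
probabilistic functional links) carries signal that per-gene features alone
do not.

The package is aimed at computational biologists who have (a) a weighted
undirected gene–gene edge list, (b) lists of known positive and negative
genes, and (c) a per-gene feature table (e.g. tissue expression), and who
want ranked candidate genes with honest cross-validated performance
estimates.

## The model

The method ("deepRW") learns two complementary node representations over
the gene network `G = (V, E)` with symmetric weighted adjacency `A` and
fuses them for classification:

1. **DeepWalk branch.** Truncated random walks sample vertex sequences
   `[v_1, v_2, ...]`, stepping from `v_i` to a neighbour with probability
   proportional to the edge weight. A skip-gram model with window `W` is
   trained on the walk corpus under the objective

       L_{v_i} = -log P(v_{c_1}, ..., v_{c_W} | v_i) = -Σ_j log P(v_{c_j} | v_i)

   (estimated by negative sampling; the full-softmax loss is retained as a
   probe, see `skipgram_loss()`), yielding one embedding vector per gene.

2. **GCN branch.** A graph convolutional encoder propagates the node
   feature matrix `X` through the symmetrically normalized augmented
   adjacency: with `A' = A + I` and `D' = diag(rowSums(A'))`, each layer
   computes

       X' = σ( D'^(-1/2) A' D'^(-1/2) X W )

   with `σ(x) = max(0, x) + 0.2 min(0, x)` (leaky ReLU). Three layers are
   the default; deeper stacks over-smooth (representations collapse toward
   a common value), which `gcn_forward()` lets you demonstrate directly.

The two representations are concatenated per gene and classified by a small
feed-forward network (affine → batch normalization → leaky ReLU twice, then
a 2-way softmax), trained jointly with the GCN under binary cross-entropy
`-y log p - (1-y) log(1-p)` using Adam and validation-loss early stopping.

Evaluation is repeated stratified 10-fold cross-validation with AUROC and
AUPR, against a random-walk-with-restart (RWR) baseline and three ablations
(`withoutGCN`, `withoutDeepWalk`, `dnnOnly`). A planted-partition synthetic
generator (`simulate_network()`, `simulate_features()`) reproduces the
method's statistical assumptions at desk scale, so the whole pipeline is
testable without downloading DisGeNET/HumanNet/BioGPS.

## Worked example

```r
library(deeprw)

cfg <- simulation_config(n_pos = 60, n_neg = 60, seed = 42)
sim <- simulate_network(cfg)
features <- simulate_features(sim$labels, cfg)
sim$network
#> gene_network: 120 nodes, 439 edges

corpus <- generate_walks(sim$network, walks_per_node = 10,
                         walk_length = 40, seed = 42)
corpus
#> walk_corpus: 1200 walks of length 40 over 120 nodes
emb <- train_skipgram(corpus, dim = 64, window = 10, iterations = 10,
                      seed = 42)

rc <- run_config(k = 5, repeats = 2, max_epochs = 80, patience = 15,
                 batch_size = 0, learning_rate = 5e-3, seed = 42)
bundle <- list(network = sim$network, features = features,
               labels = sim$labels)
run_cv("deepRW", bundle, rc)
#> eval_report [deepRW]: 10 folds, mean AUROC 0.9931, mean AUPR 0.9938
run_cv("rwr", bundle, rc)
#> eval_report [rwr]: 10 folds, mean AUROC 0.9472, mean AUPR 0.9568
```

The two reports hold one (AUROC, AUPR) pair per fold of each repeat
(5 folds x 2 repeats here) and their arithmetic means: on this strongly
separable simulation the fused model ranks held-out disease genes almost
perfectly (mean AUROC 0.9931), while network propagation alone (RWR) trails
it — `relative_difference(0.9931, 0.9472)` reports the gap as 4.62% of the
deepRW score. `run_cv("withoutGCN", ...)` and
`run_cv("withoutDeepWalk", ...)` isolate each branch's contribution, and
`layer_ablation()` repeats the evaluation at GCN depths 2, 3 and 4.

A command-line wrapper with the same functionality ships in
`inst/cli/deeprw.R` (subcommands `simulate`, `embed`, `train`, `evaluate`,
`predict`).

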