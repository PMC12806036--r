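# pepfusion

Multi-label classification of therapeutic peptides from sequence alone, by
fusing features at three granularities:

* an **atomic branch** — peptide → SMILES (built-in condensation table,
  canonical-equivalent to standard toolkit conversion) → token stream →
  pluggable transformer encoder → fully connected head;
* an **amino-acid branch** — learned residue embeddings + sinusoidal
  positions → multi-head self-attention → multi-width text convolutions
  (widths 2–5, global max-pool), in parallel with a Chou–Fasman
  secondary-structure pathway (embedding → TextCNN, no attention), merged
  by a feed-forward block;
* a **relational branch** — a k-mer hypergraph over the corpus (nodes =
  5-mers, hyperedges = sequences, tf-idf incidence weights) processed by a
  two-stage hypergraph attention network (HyperGAT): attention-weighted
  node→edge and edge→node updates, a final edge update and projection.

Branch features are concatenated (any subset can be disabled, giving the
single- and two-branch ablation architectures), passed through fully
connected fusion layers and mapped to 21 independent sigmoid outputs —
one per functional class (antibacterial ABP, anticancer ACP, antiviral
AVP, cell-penetrating CPP, …) — thresholded at 0.5.

For hyperedge $e$ with member nodes $v$, the edge update is

```
beta[v,e] = softmax_{v in e}( w[v,e] * LeakyReLU( <W'v h_v , W'e h_e> ) )
h'_e      = ELU( sum_{v in e} beta[v,e] * W'v h_v )
```

with the symmetric node update over the hyperedges containing `v`. The
`w[v,e]` are tf-idf weights (k-mer count in the sequence × log inverse
document frequency). Evaluation uses the five standard sample-averaged
multi-label metrics: precision, coverage, accuracy (Jaccard), absolute
true (exact set match) and absolute false.

Everything is testable offline: a synthetic generator emulates the real
benchmark's shape (5–50-mers, 21 classes, heavy imbalance, label-linked
sequence motifs), and all neural blocks carry hand-derived backprop
validated by finite differences plus brute-force oracles. Hot loops
(attention, convolution gather/scatter, hypergraph updates) are compiled
RcppArmadillo kernels.

## A worked example

```r
library(pepfusion)

# a synthetic 8-class benchmark with motif noise
data  <- generate_peptides(2000, n_classes = 8, noise_rate = 0.05, seed = 101)
split <- train_test_split(data, 0.8, seed = 1)

model <- train_pepfusion(split$train, tiny_config(8, epochs = 30), seed = 1)
pred  <- predict(model, split$test)
multilabel_metrics(split$test$labels, pred$.pred)
#> # A tibble: 1 × 7
#>   precision coverage accuracy absolute_true absolute_false n_samples n_labels
#>       <dbl>    <dbl>    <dbl>         <dbl>          <dbl>     <int>    <int>
#> 1     0.924    0.855    0.848         0.765         0.0381       400        8
```

Read the columns as: 92% of predicted labels are correct (precision), 86%
of true labels are recovered (coverage), the per-peptide Jaccard overlap
between predicted and true label sets averages 0.85, 76% of peptides get
their label set *exactly* right (absolute true), and about 4% of
label-slots per peptide are wrong (absolute false). `tidy(model)`,
`glance(model)` and `autoplot(model)` summarize the fit; `save_pepfusion()` /
`load_pepfusion()` round-trip the model byte-identically.

A command-line interface wraps the same functions
(`inst/cli/pepfusion`): `generate`, `train`, `predict` (TSV of
probabilities and calls) and `evaluate` (metrics as table and JSON), all
seeded through `--seed`.

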