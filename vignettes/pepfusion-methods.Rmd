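---
title: "Multi-granularity feature fusion for therapeutic peptide classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-granularity feature fusion for therapeutic peptide classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Therapeutic peptides — short amino-acid sequences of roughly 5–50 residues —
often carry several activities at once: a single peptide can be
antibacterial, anticancer and anti-inflammatory simultaneously. Predicting
the full *set* of activities from sequence is therefore a multi-label
classification problem over (by default) 21 functional classes, with heavy
class imbalance: in the reference benchmark layout, 13 of the 21 classes
have at most a few hundred examples while 4 have more than a thousand.

`pepfusion` attacks this with features at three granularities, fused into a
single sigmoid multi-label classifier:

1. **Atomic branch.** The peptide is converted to its SMILES string by
   condensation of a built-in residue table (one water per peptide bond,
   L-stereocenters included; the output is canonical-equivalent to standard
   toolkit sequence→molecule conversion). The token stream is encoded by a
   pluggable sequence encoder — by default a small randomly initialized
   transformer (multi-head self-attention + feed-forward blocks with
   residual/layer-norm) — mean-pooled over real tokens and passed through
   two fully connected layers with a dropout between them. The encoder is a
   *contract object*, so a pretrained chemistry language model can be
   plugged in without changing any downstream shape.
2. **Amino-acid branch.** Residues are integer-encoded (A = 1, C = 2, …,
   alphabetical order over the 20 letters), padded with 0 or truncated at
   the N-terminal side to a fixed window of n = 50, embedded (default
   d = 192), combined with sinusoidal positions, passed through one
   multi-head self-attention block and a multi-width text convolution
   (filter widths 2–5, global max-pool). In parallel, the Chou–Fasman
   secondary-structure string (helix/sheet/turn/coil, encoded 0–3, pad = 4)
   is embedded and passed through a TextCNN *without* attention — the
   structure string is a coarse heuristic signal and an attention block
   there mostly amplifies its noise. A feed-forward block merges the two
   pathways.
3. **Relational branch.** Overlapping k-mers (default k = 5, stride 1) of
   all training sequences become the nodes of a hypergraph; every sequence
   is a hyperedge incident to its k-mers. A two-stage hypergraph attention
   network (HyperGAT) alternates edge updates (nodes → hyperedge, scores
   weighted by tf-idf) and node updates (hyperedges → node); a final edge
   update and linear projection yield one feature per sequence. This branch
   sees *between-sequence* structure that the other two cannot.

The three branch features are concatenated (any subset can be disabled,
giving the seven ablation architectures), passed through fully connected
fusion layers, and mapped to independent per-class sigmoid probabilities,
thresholded at 0.5 (ties count as positive).

## The HyperGAT update rules

With node features $h_v$ and edge features $h_e$, both update stages share
one attention pattern. For the edge update of edge $e$:

$$\beta_{ve} = \mathrm{softmax}_{v \in e}\!\big(w_{ve}\,
  \mathrm{LeakyReLU}(\langle W'_v h_v, W'_e h_e\rangle)\big), \qquad
  h'_e = \sigma\Big(\sum_{v \in e} \beta_{ve} W'_v h_v\Big)$$

and symmetrically for the node update over the edges containing $v$ (with
unit weights and matrices $W_v, W_e$). $\sigma$ is an ELU and the LeakyReLU
slope defaults to 0.2. Three readings were genuinely open and are resolved
as follows:

* The elementwise product in the published attention coefficient is read as
  an inner product (elementwise product then sum) — the minimal reading
  that yields a scalar score; it is also standard attention practice.
* The update order is edge-then-node per layer, because the node update
  consumes edge features that are otherwise undefined at layer one; initial
  edge features are the mean of member-node embeddings.
* "Frequency and diversity" weighting is realized as tf-idf on the
  (edge, node) incidences — tf is the k-mer count within the sequence,
  idf is $\ln(|E|/\mathrm{df})$ — injected multiplicatively into the
  pre-softmax edge-update scores.

Training is transductive over the training-set hypergraph. At prediction
time new sequences attach to the *frozen* vocabulary
(`inference_hypergraph()`): unseen k-mers map to a single UNK node with
idf 0, and df/idf stay at their training values, so no information leaks
from the test set into the graph weights. The inference graph is built once
per `predict()` call over the full query set; queries that share k-mers
share attention neighborhoods, which is the transductive flavor of the
method. Probabilities do not depend on any internal batching.

## Chou–Fasman implementation

The classical propensity table (ships as a CSV under `inst/extdata/`, so
the numbers are auditable) drives the standard rules: helix nucleation in
6-residue windows with ≥ 4 residues above propensity 100, sheet nucleation
in 5-windows with ≥ 3 above 100, both extended while the advancing
4-residue window keeps a mean ≥ 100; helix/sheet overlaps go to the higher
mean propensity over the overlapping stretch; a turn is called at positions
i..i+3 when the bend-frequency product exceeds 7.5e-5 and the mean turn
propensity exceeds 100 and both competing means. The precedence — helix and
sheet first, turns fill what remains, coil elsewhere — is a documented
package choice; the published heuristic leaves it open. A second,
deliberately loop-naive rule evaluator lives in the test suite and must
agree with the vectorized implementation on random sequences.

## Loss, optimizer, and two numerical choices that matter

**Loss.** Binary cross-entropy with per-class weights
$w_c = N/(C\,\mathrm{count}_c)$ applied to the *positive* terms:
$-(w_c\, y \log p + (1-y)\log(1-p))$. Weighting both terms looks natural
but leaves the no-signal optimum of each sigmoid at the class prevalence —
it amplifies a class's gradient without ever favoring positive calls, and a
model can sit at "predict the marginals" indefinitely. Positive-term
weighting is the standard remedy for imbalance and is what the class-weight
definition is for. Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$
before the logarithm.

**Positional amplitude.** Fixed sinusoidal positions have unit amplitude;
token embeddings are initialized small. Two measures keep the token signal
from being drowned: embeddings are scaled by $\sqrt d$ before the positions
are added (standard transformer practice), and the positional matrix is
damped by `pos_scale` (default 0.3) at the branch inputs. The damping
matters specifically for the TextCNN pathway: a convolution over
position-dominated inputs loses translation invariance (the same motif at
different offsets produces different responses), and at small model sizes
this measurably prevents motif learning. `positional_embedding()` itself
returns the exact unit-amplitude sinusoids.

**Optimizer.** Adam with decoupled weight decay (biases and layer-norm
parameters exempt) and a linear warmup (10% of steps) followed by linear
decay. The configuration defaults keep the published settings where stated
— batch 128, learning rate 5e-6, 30 epochs — but 5e-6 is a *fine-tuning*
rate appropriate when a pretrained atomic encoder is plugged in;
`tiny_config()` uses 1e-3 for random-init training. A non-finite loss
aborts with a diagnostic rather than continuing to train on NaNs.

All hand-derived gradients (attention, layer norm, text convolution,
hypergraph attention, fusion) are validated against central finite
differences in the test suite, and the HyperGAT stack against a
brute-force double-loop evaluator on small random hypergraphs.

## Evaluation metrics

Five sample-averaged multi-label metrics: precision
$\frac1N\sum |y\cap\hat y|/|\hat y|$, coverage
$\frac1N\sum |y\cap\hat y|/|y|$, accuracy (Jaccard)
$\frac1N\sum |y\cap\hat y|/|y\cup\hat y|$, absolute true (exact set match),
and absolute false $\frac1N\sum (|y\cup\hat y|-|y\cap\hat y|)/M$. Two edge
conventions: an empty *predicted* set contributes 0 to precision
(abstention is penalized, not skipped), and absolute false carries the
$1/N$ average — the printed form of the definition omits it, but reported
magnitudes are only consistent with averaging. The invariant chain
`absolute_true ≤ accuracy ≤ min(precision, coverage)` holds by
construction and is property-tested. An all-zero *true* row is an error
(coverage is undefined), which is why training records must carry at least
one label.

## The synthetic generator — what it emulates and what it does not

`generate_peptides()` emulates the benchmark's *structure*: lengths uniform
on 5–50, multi-hot labels with mean label count 1.3 (1 + Poisson, class
inclusion proportional to imbalance weights of 5 / 2.5 / 1 for
abundant / medium / rare groups, mirroring the published class-size bands),
and one class-specific sequence motif implanted per positive label. Motifs
are random 5-mers (pairwise edit distance ≥ 2), matching the hypergraph's
k = 5 so that a single hypergraph node can carry a whole class signal;
implants never overlap, so at `noise_rate = 0` a trivial motif matcher
achieves absolute true 1.0 — an upper-bound oracle for any learned model.
Background residues are uniform over the 20 letters (configurable).

What it deliberately does not emulate: real amino-acid composition,
physicochemical property gradients, homology between related peptides, or
label correlations beyond shared motifs. Passing the learning tests
therefore shows the architecture can extract planted, localized,
label-linked sequence signal under class imbalance and 5% motif
corruption — not that it reaches any particular accuracy on real peptide
benchmarks.

## Problem sizes used by the tests and the reproduction script

The package's own experiments run a deliberately small instantiation
(`tiny_config()`): branch widths of 16–32, a one-layer atomic encoder over
a 48-token SMILES window, 8 filters per convolution width and
32-dimensional branch features, trained for 30 epochs on 2000 synthetic
peptides over 8 classes at `noise_rate = 0.05` with an 80/20 split. At this
scale the full three-branch model trains in roughly two minutes per seed on
one CPU core while exercising every architectural element. The learning
check averages three seeds and compares against a permutation null — the
same architecture retrained on permuted training labels, which collapses to
near-zero exact-match because a no-signal model predicts sub-threshold
marginal probabilities everywhere.

## Known limitations

* The atomic branch ships without pretrained weights (they are not
  redistributable here); with the random-init tiny encoder it contributes
  little beyond regularization, which mirrors the published finding that
  the atomic branch is the weakest of the three.
* Chou–Fasman is a 1970s heuristic; its output is used as a coarse input
  feature, not as a structure prediction.
* The SMILES table covers the 20 canonical L-amino acids; modified or
  cyclic peptides are out of scope.
* UNK-node embeddings receive no gradient during transductive training and
  stay at initialization; predictions for sequences dominated by unseen
  k-mers lean on the other two branches.
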