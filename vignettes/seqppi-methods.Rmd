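---
title: "seqppi: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqppi: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Protein–protein interactions (PPIs) in action-annotated resources such as
STRING carry *types*: a pair of proteins may be linked by activation,
binding, catalysis, expression, inhibition, post-translational modification
(ptmod), and/or reaction. `seqppi` treats typed PPI prediction as an
inductive multi-label link-prediction problem on an undirected protein
graph, using only amino-acid sequence as node input: given training
interactions, predict the 7-dimensional label vector of unseen pairs —
including pairs whose proteins never occur in the training graph.

## Model

The model is a differentiable pipeline trained end to end with Adam on a
summed multi-task binary cross-entropy. All of it — layers, backward passes
and the optimizer — is implemented in base R on top of BLAS matrix
products.

**Residue encoding (13 = 5 + 8).** Each residue is a concatenation of two
subembeddings. The first is a 5-dimensional co-occurrence vector from a
skip-gram model with negative sampling trained on the protein corpus; the
vocabulary is built from overlapping 3-mer windows. Two readings of that
corpus are implemented: the default tokenizes single residues with a
context window of one on each side (so a centre token's context is exactly
its covering 3-mer, giving one vector per residue directly), and a `kmer`
mode embeds 3-mer tokens and averages the up-to-three vectors covering a
position. The second subembedding one-hot-encodes the residue's
physicochemical class under the conjoint-triad grouping of the 20 canonical
amino acids into 7 classes — {A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W},
{R,K}, {D,E}, {C} — with an eighth catch-all class for selenocysteine (U),
pyrrolysine (O) and any unrecognized letter. We read the conventional
"5 + 7 + 1" dimension count as 5 co-occurrence dimensions plus an 8-way
one-hot (7 canonical classes + 1 catch-all): that is the only reading under
which every letter is encodable and the dimensions total 13. Sequences are
truncated to `max_length` (default 2000) residues from the right. Unseen
tokens map to the zero co-occurrence vector so novel proteins always
encode. By default the skip-gram corpus contains only proteins incident to
training edges, keeping test sequences out of every trained component.

**Inception sequence encoder.** The residue matrix (13 × L) passes through
`n_submodules` (default 4) identical Inception-style sub-modules. Each
concatenates four length-preserving branches: 1-D convolutions with kernel
sizes 1, 3 and 5 (`channels` output channels each, default 32), and a
temporal max-pool (k = 3) followed by a 1×1 projection. Same-padding with
zeros, stride 1; per-branch channel normalization over the temporal axis
(toggleable) and ReLU. Because the interior wiring of the sub-modules is a
design choice, we stack four identical blocks; 2-D kernel factorizations
from the image-domain Inception variants are deliberately not used — the
input is one-dimensional, so k ∈ {1,3,5} kernels already realize the
multi-scale idea. A final global pooling over the temporal axis (average by
default, maximum by option) yields a fixed node feature vector of dimension
d = 3·channels + pool_channels, independent of sequence length.

**Graph propagation (GIN).** Proteins are nodes; training interactions —
and only training interactions — are edges, with multi-label edges
collapsed to one structural edge. One Graph Isomorphism Network layer
(configurable) updates every node:

    g_p <- MLP((1 + eps) * g_p + sum_{p' in N(p)} g_{p'})

with eps learnable (initialized 0) and a two-layer ReLU MLP of width d.
Test-only proteins sit in the graph as isolated nodes: they propagate their
own encoder feature and nothing else, which is exactly the information
available for an unknown protein at deployment.

**Pair head.** For a candidate pair, the two updated node features form a
2-row matrix refined by single-head scaled dot-product self-attention,
`softmax(QK'/sqrt(d_k)) V` with Q, K, V linear maps of the same input. The
scaling is kept (one of the printed forms of the attention equation omits
it; we treat the scaled form as normative and expose a flag to disable).
The refined pair (e1, e2) is scored by the feature relational reasoning
(FRN) layer: per tensor slice i of k (default 8),

    F_i = tanh( (e1 + e2)' W[i] (e1 - e2)  +  (V [e1; e2])_i * cos(e1, e2)  +  b_i )

The bilinear term contracts the pair's sum against its difference — it is
exactly antisymmetric under swapping the arguments and vanishes when
e1 = e2 — while the standard linear layer on the concatenation is weighted
by the pair's cosine similarity, injecting explicit distance/direction
information. The classic neural tensor network (NTN) scorer
`u' tanh(e1' W[1:k] e2 + V [e1; e2] + b)` is provided as a drop-in
alternative for ablation; in that mode the classifier consumes the
pre-projection k-vector, the natural analogue of the FRN output (the FRN
form prints no `u` projection, so it returns the k-vector as-is).

**Classifier and loss.** The classifier input defaults to the concatenation
of the k-dim relational output with the elementwise product e1 ∘ e2.
The two printed signals for the classifier input — "FC(e1 · e2)" and the
relational output — are both preserved this way; flags select either alone,
which is how the ablation grid is run. We read "e1 · e2" as the elementwise
product: an inner product would hand the classifier a single scalar. A
hidden linear stage with ReLU and an output linear map produce 7 logits,
squashed by sigmoids into per-type probabilities; a label is predicted at
probability ≥ 0.5 (configurable — the thresholding convention for micro-F1
is not fixed by the method, so the conventional 0.5 is adopted). The loss
sums `-y log p - (1-y) log(1-p)` over all training pairs and the 7 label
tasks, with probabilities clamped to [1e-7, 1 - 1e-7].

## Splits and evaluation

20% of edges are held out (ratio configurable). Three schemes:

* **random** — uniform edge sample, exactly `round(0.2 |E|)` edges;
* **bfs / dfs** — a random root protein is traversed breadth- or
  depth-first; each visited node claims its incident edges into the test
  set one edge at a time, stopping as soon as the count reaches
  `0.2 |E|` (so the overshoot is at most the stop-rule rounding); exhausted
  components trigger a restart at a fresh random root. Claiming edges one
  at a time is our declared stop rule — the cited protocols leave the
  overshoot behaviour unstated, and the one-at-a-time rule makes the test
  fraction exact up to ceiling.

Traversal splits concentrate test edges around the visited neighbourhood,
forcing inductive prediction. Test edges are further stratified:
*homologous* (both endpoints appear in some training edge) vs *unknown*
(at least one endpoint unseen). Evaluation pools true/false
positive/negative counts over all 7 labels and pairs and reports
micro-averaged precision, recall and F1; zero denominators yield 0, never
NaN, and empty strata are reported as "n/a" rather than 0. Macro-F1 and
per-label counts are supplementary outputs.

## Synthetic benchmark

`sim_config()` describes a STRING-like benchmark small enough for a laptop
yet structured enough to exercise every component. Defaults: 50 proteins of
50–200 residues over the canonical alphabet (U/X letters at rate 0.001 per
position), 150 distinct edges, zero label noise. Each of the 7 interaction
types is tied to a distinct 5-mer motif; a protein carries 0–3 motif types,
each planted twice (functional motifs recur in real sequences, and repeated
copies give the pooled encoder signal realistic redundancy). An edge's
label set is `{t : both endpoints contain motif t}`, with a single random
fallback label when empty — so ground-truth label sets are never empty, and
with zero noise the sequence→label mapping is a deterministic function of
the generated data. Edges are sampled with preferential attachment
(endpoint weight degree + 1), producing the right-skewed hub structure of
real PPI networks; that skew is what makes BFS/DFS splits behave
qualitatively differently from random splits. Motif containment is always
recomputed from the final sequence (later plants may overwrite earlier
ones), so labels and sequences can never disagree.

What the generator does *not* emulate: realistic amino-acid composition,
homologous sequence families, confidence-scored edges, or negative pair
sampling. Passing the end-to-end tests therefore demonstrates that the
pipeline can extract sequence-determined interaction rules and memorize
pair structure on a faithful miniature — not that it attains any particular
accuracy on real STRING-scale data.

## Numerical and optimization choices

* **Initialization.** Glorot-uniform weights; GIN eps at 0; classifier
  output biases start at the empirical base-rate logits of the training
  labels, so a sparse multi-label head begins calibrated instead of
  spending its first epochs descending to the all-negative regime.
* **Node-feature calibration.** A randomly initialized convolutional
  encoder followed by global pooling emits features with a large common
  mode and only a few percent of between-protein variation, which makes the
  joint optimization crawl. At initialization the package therefore
  computes a fixed affine (center, scale) standardizing the pooled features
  across the *training-graph* proteins, and applies it as a model constant
  thereafter. It is data-dependent initialization in the LSUV tradition:
  computed once, never updated, never touching test information, and
  inference-safe because it does not depend on the batch.
* **Optimizer.** Adam (beta1 0.9, beta2 0.999, eps 1e-8) on the summed
  loss; batches are sets of training pairs while the graph step always runs
  full-graph. An optional cosine annealing of the learning rate to zero
  damps the late-stage oscillation of full-batch Adam on small data sets.
  Early stopping is off by default (fixed-epoch training).
* **Determinism.** Every stochastic step (skip-gram sampling, weight
  initialization, batch shuffling, split sampling, sequence generation)
  derives from the user seed through an isolated RNG scope; two fits with
  the same seed and thread count are bitwise identical. The non-finite-loss
  guard aborts with a diagnostic rather than silently continuing.
* **Ties and edges.** Max-pooling ties resolve to the earliest temporal
  offset; the zero-norm cosine is defined as 0 (no direction information;
  the corresponding gradient is also 0); length-1 sequences are valid
  (same-padding supplies the zero context); BCE clamping keeps the loss
  finite at saturated probabilities.

## Scale of the built-in experiments

The packaged validation experiment (`motif_recovery_experiment()`) trains
the full model on the default 50-protein / 150-edge noise-free benchmark
under a random and a BFS split. Its training configuration is deliberately
desk-scale: 8 channels per branch (d = 32), classifier hidden width 64,
60-pair batches, cosine-annealed Adam at 0.004 for 200 epochs. The
large-scale defaults in `ppi_control()` (learning rate 0.001, batch 2048,
300 epochs, 32 channels) reflect the settings appropriate for
hundred-thousand-edge corpora and remain the package defaults. Two
observations from the experiment are worth restating as expectations rather
than numbers: the noise-free training set is essentially memorized
(micro-F1 near 1), and the random split scores above the BFS split, whose
test edges concentrate on proteins the training graph barely knows. About
60% of the default benchmark's edges carry a fallback label, learnable only
by pair memorization, which is why test-set micro-F1 on this benchmark sits
far below the training value for every scheme.

## Limitations

* One attention head and one shared relational parameter set; no
  per-label-type adjacency or relation-specific tensors.
* Full-graph propagation per step: fine for thousands of proteins, not for
  STRING-scale graphs without neighbour sampling.
* The skip-gram, convolution and graph layers are plain R; at
  hundreds-of-thousands of edges a compiled backend would be needed.
* Homology-aware splitting (sequence-identity clustering) is out of scope;
  the homologous/unknown stratification is graph-based, not
  alignment-based.
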