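# seqppi

Sequence-based multi-label protein–protein interaction (PPI) prediction in
R. Given protein sequences and a training set of typed interactions
(activation, binding, catalysis, expression, inhibition, post-translational
modification, reaction — the seven action types of STRING-style data),
`seqppi` predicts which of the seven types link an arbitrary protein pair,
including pairs involving proteins absent from the training graph. It is
aimed at computational biologists studying inductive link prediction on
interaction networks, and at method developers who want a compact, fully
inspectable reference implementation of this model family — every layer and
every backward pass is plain R.

## The model

The pipeline, trained end to end with Adam on a multi-task binary
cross-entropy:

1. **Residue embedding (13-dim).** Each amino acid is the concatenation of
   a 5-dim skip-gram co-occurrence vector (negative sampling, overlapping
   3-mer context) and an 8-way one-hot of its conjoint-triad
   physicochemical class (7 canonical classes; U, O and unknown letters
   share an eighth).
2. **Inception sequence encoder.** Four stacked sub-modules of parallel
   1-D convolutions with kernels 1, 3, 5 plus a max-pool branch,
   concatenated channel-wise; global pooling yields a fixed node feature
   `g_p` per protein regardless of length.
3. **Graph propagation (GIN).** On the training-edge graph,
   `g_p ← MLP((1+ε) g_p + Σ_{p′∈N(p)} g_{p′})` with learnable ε. Test
   proteins sit as isolated nodes — no test edge ever enters the adjacency.
4. **Pair head.** Scaled dot-product self-attention refines the pair
   `(e₁, e₂)`, which is scored by the feature relational reasoning (FRN)
   layer, per tensor slice `i`:

       F_i = tanh( (e₁+e₂)ᵀ W⁽ⁱ⁾ (e₁−e₂) + (V[e₁;e₂])_i · cos(e₁,e₂) + b_i )

   The classic NTN bilinear scorer `uᵀ tanh(e₁ᵀW⁽¹ᐧᐧᵏ⁾e₂ + V[e₁;e₂] + b)`
   is available as an ablation alternative.
5. **Classifier.** The FRN output concatenated with `e₁∘e₂` feeds a
   ReLU-hidden fully connected layer producing 7 sigmoid probabilities;
   labels are predicted at probability ≥ 0.5.

Evaluation is micro-averaged F1 over all 7 label tasks, with inductive
Random/BFS/DFS 80/20 edge splits and a homologous/unknown stratification of
test edges. A motif-planted synthetic PPI generator
(`simulate_ppi_data()`) makes the whole pipeline testable without any
external download.

## Worked example

```r
library(seqppi)

dat   <- simulate_ppi_data(sim_config(n_proteins = 30, n_edges = 60,
                                      length_range = c(40, 80), seed = 42))
split <- traversal_split(dat$edges, "bfs", 0.2, seed = 42)
split
#> PPI edge split  scheme=bfs  seed=42
#>   train: 48 edges
#>   test:  12 edges (4 homologous, 8 unknown)

fit <- ppi_fit(dat$proteins, dat$edges, split,
               ppi_control(channels = 8, hidden = 64, learning_rate = 0.004,
                           lr_schedule = "cosine", batch_size = 60,
                           epochs = 60, eval_every = 20, seed = 42))
fit
#> Sequence-based multi-label PPI prediction model
#>   proteins: 30   train edges: 48   test edges: 12 (bfs split, seed 42)
#>   components: inception+attention+frn   d_node: 32   slices: 8
#>   epochs: 60   final loss: 74.2523   train micro-F1: 0.5676

ppi_evaluate(fit)
#> overall:    micro-F1 0.1429  (precision 0.5000, recall 0.0833; TP 1, FP 1, FN 11 over 12 pairs)
#> homologous: micro-F1 0.3333  (precision 0.5000, recall 0.2500; TP 1, FP 1, FN 3 over 4 pairs)
#> unknown:    micro-F1 0.0000  (precision 0.0000, recall 0.0000; TP 0, FP 0, FN 8 over 8 pairs)
```

The split report shows the BFS traversal concentrating test edges on
proteins the training graph barely sees (8 of 12 test edges have an
endpoint never observed in training). After only 60 epochs on 48 training
pairs the model has learned a bit over half of the training label
decisions (micro-F1 0.57); generalization is limited on the harder unknown
stratum, as expected for an inductive BFS split of a 60-edge toy graph —
longer schedules and the package defaults in `motif_recovery_experiment()`
drive the training fit to ~0.99. Per-pair predictions are ordinary data
frames:

```r
predict(fit)[1:3, ]
#>        protein_a protein_b activation binding catalysis expression inhibition  ptmod reaction     labels
#> P011        P011      P025     0.1470   0.283   0.06625     0.0994     0.1425 0.0898   0.0296
#> P014        P014      P018     0.2081   0.266   0.00395     0.5154     0.0877 0.0167   0.0211 expression
#> P014.1      P014      P029     0.0434   0.567   0.03893     0.0303     0.2097 0.0808   0.0163    binding
```

`plot(fit)` draws the loss and micro-F1 training curves; `coef()`,
`residuals()`, `summary()` and `simulate()` behave as for other R model
objects.

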