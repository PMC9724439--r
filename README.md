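# ppihop

Multi-label prediction of protein–protein interaction (PPI) types with a
multi-hop graph neural network over the PPI network and a multi-head
self-attention encoder over amino-acid sequences — implemented in pure R on
a small, gradient-checked reverse-mode autodiff engine.

## Who this is for

Computational biologists and method developers who want a transparent,
CPU-scale, fully seeded implementation of the "sequence encoder + twin GIN
branches" family of PPI-type predictors, together with the field's
evaluation protocol: random/BFS/DFS edge splits, negative sampling at
configurable ratios, and micro-F1.

## The model

Interactions carry one or more of the seven STRING "mode" types (ptmod,
catalysis, reaction, activation, expression, binding, inhibition), so each
interacting pair `(i, j)` has a 7-dim multi-hot label `y_ij`.

1. **Sequence encoder.** Each residue is a 13-dim vector (5-dim
   co-occurrence + 8-dim one-hot physicochemical class). A kernel-3 1-D
   convolution, channel normalization, max pooling, a multi-head
   self-attention transformer block, global average pooling and a fully
   connected layer produce a fixed-width feature per protein.
2. **Multi-hop graph encoder.** The node features (sequence feature +
   structural descriptors, width 256) feed two identical GIN branches:
   one over the PPI adjacency `A`, one over the two-hop adjacency

   ```
   A2 = sign(A %*% t(A)),   sign(x) = 1 if x > 0 else 0
   ```

   which connects proteins sharing an interaction partner (and adds a
   self-connection to every non-isolated node). Each GIN iteration updates
   `g_p <- MLP((1 + eps) * g_p + sum over neighbours of g_q)`. The branch
   embeddings are fused by element-wise summation.
3. **Pair classifier.** `y_hat_ij = sigmoid(FC(e_i * e_j))` (element-wise
   product, hence symmetric). Training minimizes the multi-task binary
   cross-entropy (sum over the 7 classes, mean over pairs) with Adam.
4. **Metric.** Micro-F1 pools TP/FP/FN over all classes:
   `F1 = 2 * P_m * R_m / (P_m + R_m)`.

See `vignettes/multihop-ppi-methods.Rmd` for assumptions, parameter
defaults, and design rationale.

## Worked example

```r
library(ppihop)

# 1. a synthetic PPI dataset: 60 proteins in 2 hidden groups, typed edges
dat <- synth_generate(synth_spec(n_proteins = 60, n_groups = 2,
                                 edge_density = 0.12,
                                 seq_length = c(30L, 60L), seed = 42))
g <- build_adjacency(dat$proteins, dat$interactions)
print(g)
#> <ppi_graph> 60 proteins, 194 interactions

# 2. the two-hop network: proteins sharing an interaction partner
h2 <- two_hop_adjacency(g)
cat("two-hop edges (incl. self-connections):", sum(h2$A) / 2, "\n")
#> two-hop edges (incl. self-connections): 809

# 3. a random edge split and 1:1 negatives
split <- split_edges(g, partition_spec("random", 0.2, seed = 1))
print(split)
#> <ppi_partition> scheme=random train=155 test=39 root=-
negatives <- sample_negatives(g, ratio = 1, seed = 1)

# 4. train a small model and evaluate held-out micro-F1
cfg <- ppihop_config(
  paase = paase_config(conv_channels = 32, pool_size = 8, n_heads = 2,
                       d_qk = 16, d_v = 16, d_seq = 64),
  gin = gin_config(iterations = 2, hidden = 64, d_emb = 64),
  hops = c(1, 2), max_len = 100
)
dataset <- ppihop_dataset(dat$proteins, dat$interactions, negatives, cfg)
model <- ppihop_model(cfg, dataset, seed = 1)
fit <- ppihop_train(model, dataset, split,
                    train_config(learning_rate = 0.005, weight_decay = 3e-3,
                                 batch_size = 512, max_epochs = 20,
                                 plateau_patience = 20,
                                 early_stop_patience = 20, seed = 1))
print(fit$final)
#> <metric_report> micro-F1 0.6051 (precision 0.5043, recall 0.7564)
```

The printed micro-F1 is computed on the held-out test edges: at this
deliberately tiny scale (60 proteins, 20 epochs) the model recovers a
majority of the planted interaction types. On the canonical 200-protein
fixture (`planted_recovery_dataset()`) the same architecture trained under
`planted_recovery_protocol()` recovers the planted labels with held-out
micro-F1 above 0.9 (see below).

Real data in the STRING dialects is read with `read_sequences()`
(FASTA or two-column TSV) and `read_interactions()` (three-column TSV of
`id  id  type` rows, merged to multi-hot records).

A command-line front end wrapping the same functions ships in
`inst/cli/ppihop.R` with subcommands `synth`, `graph`, `split`, `train`,
`evaluate`, `ablate`; every run writes a JSON manifest (seed, config hash,
input hashes) sufficient to reproduce it bit-for-bit on CPU.

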