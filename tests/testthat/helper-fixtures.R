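# Shared in-code fixtures: tiny random graphs, sequences and model
# configurations sized for fast unit tests.

random_sequence <- function(len) {
  paste(sample(ppihop:::CANONICAL_AA, len, replace = TRUE), collapse = "")
}

random_protein_table <- function(n, len_range = c(10L, 20L)) {
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sequence = vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                      random_sequence, ""),
    stringsAsFactors = FALSE
  )
}

# random symmetric binary adjacency with zero diagonal
random_adjacency <- function(n, p = 0.2) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1L
  A + t(A)
}

graph_from_A <- function(A, ids = sprintf("P%03d", seq_len(nrow(A)))) {
  structure(list(proteins = ids, A = A), class = "ppi_graph")
}

# interaction table over the given graph's edges with random non-empty labels
random_interactions_for <- function(g) {
  e <- ppihop:::graph_edges(g)
  vocab <- ppi_label_types()
  lab <- matrix(rbinom(nrow(e) * 7L, 1L, 0.3), nrow(e), 7L,
                dimnames = list(NULL, vocab))
  none <- rowSums(lab) == 0L
  lab[cbind(which(none), sample.int(7L, sum(none), replace = TRUE))] <- 1L
  cbind(e, as.data.frame(lab))
}

tiny_model_cfg <- function(variant = "full", hops = c(1L, 2L)) {
  ppihop_config(
    paase = paase_config(conv_channels = 6L, pool_size = 3L, n_heads = 2L,
                         d_qk = 4L, d_v = 4L, d_seq = 8L),
    gin = gin_config(hidden = 8L, d_emb = 6L, input_width = 16L),
    hops = hops, max_len = 24L, variant = variant
  )
}

tiny_dataset <- function(n = 10L, p = 0.3, seed = 7L,
                         cfg = tiny_model_cfg()) {
  set.seed(seed)
  prot <- random_protein_table(n)
  g <- graph_from_A(random_adjacency(n, p), prot$id)
  inter <- random_interactions_for(g)
  ppihop_dataset(prot, inter, negatives = NULL, cfg = cfg)
}

expect_symmetric <- function(A) expect_equal(A, t(A))
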