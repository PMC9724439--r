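# Full model assembly: configuration, parameter initialization, dataset
# preparation, and the end-to-end tape forward pass.

#' Full model configuration
#'
#' @param paase Sequence-encoder configuration ([paase_config()]).
#' @param gin GIN-branch configuration ([gin_config()]); one branch is
#'   instantiated per entry of `hops`, each with its own parameters.
#' @param hops Hop set, a non-empty subset of `c(1, 2, 3)`: which k-hop
#'   adjacencies get a GIN branch (default `c(1, 2)`, the one-hop network
#'   plus the constructed two-hop network).
#' @param max_len Sequence truncation/padding length.
#' @param variant `"full"`, `"no_pmhge"` (graph aggregation removed: a single
#'   branch over an empty adjacency, i.e. a pure MLP on node features), or
#'   `"no_paase"` (sequence encoder replaced by a trainable per-protein
#'   embedding lookup).
#' @return A `ppihop_config` list.
#' @export
ppihop_config <- function(paase = paase_config(), gin = gin_config(),
                          hops = c(1L, 2L), max_len = 512L,
                          variant = c("full", "no_pmhge", "no_paase")) {
  variant <- match.arg(variant)
  hops <- sort(unique(as.integer(hops)))
  if (!length(hops) || !all(hops %in% 1:3)) {
    stop_validation("hops must be a non-empty subset of {1, 2, 3}")
  }
  if (gin$input_width < paase$d_seq + 3L) {
    stop_validation("d_seq (%d) leaves no room for the structural block in the %d-wide node features",
                    paase$d_seq, gin$input_width)
  }
  structure(list(paase = paase, gin = gin, hops = hops,
                 max_len = as.integer(max_len), variant = variant),
            class = "ppihop_config")
}

model_branches <- function(cfg) {
  if (cfg$variant == "no_pmhge") 0L else cfg$hops
}

#' Initialize a model
#'
#' Creates the trainable parameters for the configured variant: sequence
#' encoder (or per-protein lookup), one GIN branch per hop, and the 7-class
#' pair classifier head.  Initialization is Glorot-uniform, seeded.
#'
#' @param cfg A [ppihop_config()].
#' @param dataset A [ppihop_dataset()] (sizes the lookup variant and records
#'   the protein order the model is bound to).
#' @param seed Integer seed.
#' @return A `ppihop_model` list with `cfg`, `params`, `vocab`, `proteins`.
#' @export
ppihop_model <- function(cfg, dataset, seed = 1L) {
  n <- length(dataset$graph$proteins)
  params <- with_seed(seed, {
    p <- if (cfg$variant == "no_paase") {
      list("seq.embed" = glorot(n, cfg$paase$d_seq))
    } else {
      init_paase_params(cfg$paase)
    }
    for (k in model_branches(cfg)) {
      p <- c(p, init_gin_params(cfg$gin, sprintf("gin%d", k)))
    }
    p[["head.W"]] <- glorot(cfg$gin$d_emb, 7L)
    p[["head.b"]] <- matrix(0, 1, 7L)
    p
  })
  structure(list(cfg = cfg, params = params, vocab = dataset$vocab,
                 proteins = dataset$graph$proteins),
            class = "ppihop_model")
}

#' @export
print.ppihop_model <- function(x, ...) {
  cat(sprintf("<ppihop_model> variant=%s hops={%s} params=%d\n",
              x$cfg$variant, paste(x$cfg$hops, collapse = ","),
              n_model_params(x)))
  invisible(x)
}

#' Count trainable scalar parameters
#' @param model A `ppihop_model`.
#' @export
n_model_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' Prepare a training dataset
#'
#' Precomputes everything the forward pass needs: the PPI graph, the k-hop
#' adjacencies, per-protein encoded (and truncated) residue matrices, the
#' structural feature block, and the label lookup for positive pairs.
#'
#' @param proteins data.frame with `id`, `sequence` (as from
#'   [read_sequences()]).
#' @param interactions Positive interaction data.frame (as from
#'   [read_interactions()]).
#' @param negatives Optional sampled negative pairs
#'   ([sample_negatives()]); all-zero labels.
#' @param cfg A [ppihop_config()].
#' @param table Residue embedding table.
#' @return A `ppihop_dataset` list.
#' @export
ppihop_dataset <- function(proteins, interactions, negatives = NULL,
                           cfg = ppihop_config(), table = aa_embedding_table()) {
  g <- build_adjacency(proteins, interactions)
  hops <- cfg$hops
  hop_adj <- list()
  for (k in hops) hop_adj[[as.character(k)]] <- k_hop_adjacency(g, k)$A
  encoded <- lapply(seq_len(nrow(proteins)), function(i) {
    enc <- encode_sequence(proteins[i, ], table, cfg$max_len)
    trim_encoded(enc$matrix, enc$mask, cfg$paase$kernel)
  })
  vocab <- ppi_label_types()
  structure(list(graph = g, proteins = proteins, interactions = interactions,
                 negatives = negatives, hop_adj = hop_adj,
                 struct = structural_block(g, cfg$gin$input_width - cfg$paase$d_seq),
                 encoded = encoded,
                 pack = pack_sequences(encoded, cfg$paase$kernel, cfg$paase$pool_size),
                 vocab = vocab, cfg = cfg),
            class = "ppihop_dataset")
}

# label matrix for an arbitrary set of edges: positives take their recorded
# multi-hot labels, anything else (sampled negatives) is all-zero
pair_labels <- function(dataset, edges) {
  vocab <- dataset$vocab
  lab <- matrix(0L, nrow(edges), length(vocab), dimnames = list(NULL, vocab))
  if (nrow(dataset$interactions)) {
    key <- pair_key(edges$protein_i, edges$protein_j)
    ikey <- pair_key(dataset$interactions$protein_i, dataset$interactions$protein_j)
    hit <- match(key, ikey)
    found <- !is.na(hit)
    lab[found, ] <- interaction_labels(dataset$interactions, vocab)[hit[found], , drop = FALSE]
  }
  lab
}

# edge data.frame -> m x 2 integer index matrix into the protein order
pair_index <- function(dataset, edges) {
  cbind(match(edges$protein_i, dataset$graph$proteins),
        match(edges$protein_j, dataset$graph$proteins))
}

# Full tape forward pass up to per-pair probabilities.
# pairs_idx: m x 2 integer matrix. Returns nodes (E, prob) plus leaf params.
model_forward <- function(tape, params, model, dataset, pairs_idx) {
  cfg <- model$cfg
  P <- wrap_params(tape, params)
  S <- if (cfg$variant == "no_paase") {
    P[["seq.embed"]]
  } else {
    paase_forward(tape, ad_leaf(tape, dataset$pack$X), P, cfg$paase,
                  dataset$pack)
  }
  X <- ad_cbind(tape, S, ad_leaf(tape, dataset$struct))
  E <- NULL
  for (k in model_branches(cfg)) {
    A <- if (k == 0L) matrix(0, nrow(dataset$struct), nrow(dataset$struct))
         else dataset$hop_adj[[as.character(k)]] + 0
    Ek <- gin_branch_forward(tape, X, ad_leaf(tape, A), P,
                             sprintf("gin%d", k), cfg$gin)
    E <- if (is.null(E)) Ek else ad_add(tape, E, Ek)
  }
  Ei <- ad_gather_rows(tape, E, pairs_idx[, 1L])
  Ej <- ad_gather_rows(tape, E, pairs_idx[, 2L])
  Z <- ad_mul(tape, Ei, Ej)
  logits <- ad_add(tape, ad_matmul(tape, Z, P[["head.W"]]), P[["head.b"]])
  prob <- ad_sigmoid(tape, logits)
  list(E = E, prob = prob, P = P)
}
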