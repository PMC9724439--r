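# Multi-hop graph encoder: identical GIN branches over the one-hop PPI
# network and the constructed two-hop network, sharing the same L x 256 node
# feature matrix, fused by element-wise summation.

#' GIN branch configuration
#'
#' @param iterations Number of GIN aggregation iterations per branch.
#' @param hidden Hidden width of the two-linear-layer update MLP.
#' @param d_emb Output embedding width per protein.
#' @param eps Initial value of the per-branch epsilon.
#' @param eps_learnable Whether epsilon is trained.
#' @param input_width Node-feature width consumed by the first iteration
#'   (fixed at 256 by the node-feature contract).
#' @return A `gin_config` list.
#' @export
gin_config <- function(iterations = 1L, hidden = 128L, d_emb = 64L,
                       eps = 0, eps_learnable = TRUE, input_width = 256L) {
  stopifnot(iterations >= 1L, hidden >= 1L, d_emb >= 1L)
  structure(list(iterations = as.integer(iterations), hidden = as.integer(hidden),
                 d_emb = as.integer(d_emb), eps = eps,
                 eps_learnable = isTRUE(eps_learnable),
                 input_width = as.integer(input_width)),
            class = "gin_config")
}

#' One GIN aggregation layer
#'
#' Computes `mlp((1 + eps) * g_p + sum_{p' in N(p)} g_p')` for every node p,
#' where the neighbour sum is `A %*% features`; a self-loop in `A` (as in the
#' two-hop adjacency) contributes the node's own state to the sum.
#'
#' @param features `L x d` node feature matrix.
#' @param A `L x L` binary adjacency.
#' @param eps Scalar epsilon.
#' @param mlp Update function, matrix -> matrix (default identity).
#' @return Updated node feature matrix.
#' @export
gin_layer <- function(features, A, eps = 0, mlp = identity) {
  validate_adjacency(A)
  if (nrow(A) != nrow(features)) {
    stop_validation("adjacency (%d nodes) and features (%d rows) disagree",
                    nrow(A), nrow(features))
  }
  mlp((1 + eps) * features + A %*% features)
}

# initialize one branch's parameters under `prefix` (e.g. "gin1.")
init_gin_params <- function(cfg, prefix) {
  p <- list()
  p[[paste0(prefix, ".eps")]] <- matrix(cfg$eps, 1, 1)
  d_in <- cfg$input_width
  for (it in seq_len(cfg$iterations)) {
    pre <- sprintf("%s.it%d", prefix, it)
    p[[paste0(pre, ".W1")]] <- glorot(d_in, cfg$hidden)
    p[[paste0(pre, ".b1")]] <- matrix(0, 1, cfg$hidden)
    p[[paste0(pre, ".ng1")]] <- matrix(1, 1, cfg$hidden)
    p[[paste0(pre, ".nb1")]] <- matrix(0, 1, cfg$hidden)
    p[[paste0(pre, ".W2")]] <- glorot(cfg$hidden, cfg$d_emb)
    p[[paste0(pre, ".b2")]] <- matrix(0, 1, cfg$d_emb)
    p[[paste0(pre, ".ng2")]] <- matrix(1, 1, cfg$d_emb)
    p[[paste0(pre, ".nb2")]] <- matrix(0, 1, cfg$d_emb)
    d_in <- cfg$d_emb
  }
  p
}

# tape forward for one branch: X and Aleaf are nodes, P leaf-wrapped params
gin_branch_forward <- function(tape, X, Aleaf, P, prefix, cfg) {
  H <- X
  for (it in seq_len(cfg$iterations)) {
    pre <- sprintf("%s.it%d", prefix, it)
    self_term <- ad_add(tape, H, ad_mul_scalar(tape, H, P[[paste0(prefix, ".eps")]]))
    agg <- ad_add(tape, self_term, ad_matmul(tape, Aleaf, H))
    h <- ad_add(tape, ad_matmul(tape, agg, P[[paste0(pre, ".W1")]]), P[[paste0(pre, ".b1")]])
    h <- ad_relu(tape, h)
    h <- ad_norm_cols(tape, h, P[[paste0(pre, ".ng1")]], P[[paste0(pre, ".nb1")]])
    h <- ad_add(tape, ad_matmul(tape, h, P[[paste0(pre, ".W2")]]), P[[paste0(pre, ".b2")]])
    h <- ad_relu(tape, h)
    H <- ad_norm_cols(tape, h, P[[paste0(pre, ".ng2")]], P[[paste0(pre, ".nb2")]])
  }
  H
}

#' Encode one GIN branch
#'
#' Applies `cfg$iterations` GIN layers with the two-linear-layer update MLP
#' (linear, ReLU, normalization, twice) over the given adjacency.  Branch 1
#' of the full model consumes the one-hop adjacency, branch 2 the two-hop
#' adjacency from [two_hop_adjacency()].
#'
#' @param node_features `L x input_width` matrix (see
#'   [build_node_features()]).
#' @param A Binary adjacency of the branch's graph.
#' @param cfg A [gin_config()].
#' @param params Model parameter list holding this branch's parameters.
#' @param branch Branch identifier: the hop number whose parameters
#'   (`gin<branch>.*`) to use.
#' @return `L x d_emb` embedding matrix.
#' @export
encode_branch <- function(node_features, A, cfg, params, branch = 1L) {
  validate_adjacency(A)
  if (ncol(node_features) != cfg$input_width) {
    stop_validation("node features must have width %d", cfg$input_width)
  }
  tape <- ad_tape()
  out <- gin_branch_forward(tape, ad_leaf(tape, node_features),
                            ad_leaf(tape, A + 0), wrap_params(tape, params),
                            sprintf("gin%d", branch), cfg)
  out$value
}

#' Fuse branch embeddings by element-wise summation
#'
#' @param E1,E2 Equal-shape embedding matrices.
#' @return Their element-wise sum.
#' @export
fuse_embeddings <- function(E1, E2) {
  if (!all(dim(E1) == dim(E2))) stop_validation("embedding shapes disagree")
  E1 + E2
}

# graph-level structural descriptors: normalized degree, local clustering
# coefficient, normalized two-hop degree; zero for isolated nodes
structural_descriptors <- function(g) {
  A <- g$A
  n <- nrow(A)
  deg <- rowSums(A)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  A2 <- sign01(tcrossprod(A))
  diag(A2) <- 0L
  deg2 <- rowSums(A2)
  unname(cbind(deg / max(1, max(deg)), cc, deg2 / max(1, max(deg2))))
}

#' Assemble the L x 256 node-feature matrix
#'
#' Concatenates the per-protein sequence features with a structural
#' descriptor block (normalized degree, local clustering coefficient,
#' normalized two-hop degree) and zero-pads to a total width of 256.
#'
#' @param seq_features `L x d_seq` sequence-feature matrix (rows in graph
#'   protein order).
#' @param g The `ppi_graph`.
#' @param width Total output width (default 256).
#' @return `L x width` matrix.
#' @export
build_node_features <- function(seq_features, g, width = 256L) {
  d_seq <- ncol(seq_features)
  sdesc <- structural_descriptors(g)
  if (d_seq + ncol(sdesc) > width) {
    stop_validation("sequence features too wide: %d + %d structural > %d",
                    d_seq, ncol(sdesc), width)
  }
  pad <- width - d_seq - ncol(sdesc)
  cbind(seq_features, sdesc, matrix(0, nrow(seq_features), pad))
}

# the structural + padding block alone (used by the training forward pass,
# which concatenates it to the trainable sequence features on the tape)
structural_block <- function(g, width) {
  sdesc <- structural_descriptors(g)
  cbind(sdesc, matrix(0, nrow(sdesc), width - ncol(sdesc)))
}
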