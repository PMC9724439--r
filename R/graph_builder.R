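# PPI adjacency construction, multi-hop adjacency augmentation, and negative
# sampling.

#' Build the binary PPI adjacency
#'
#' @param proteins Ordered character vector of protein ids (defines the
#'   index -> id mapping) or a data.frame with an `id` column.
#' @param positives Interaction data.frame of positive pairs.
#' @return A `ppi_graph`: list with `proteins` (ids) and `A` (N x N binary,
#'   symmetric, zero diagonal).
#' @export
build_adjacency <- function(proteins, positives) {
  if (is.data.frame(proteins)) proteins <- proteins$id
  if (anyDuplicated(proteins)) stop_validation("duplicate protein ids")
  n <- length(proteins)
  A <- matrix(0L, n, n)
  if (nrow(positives)) {
    i <- match(positives$protein_i, proteins)
    j <- match(positives$protein_j, proteins)
    if (anyNA(i) || anyNA(j)) {
      bad <- c(positives$protein_i[is.na(i)], positives$protein_j[is.na(j)])[1L]
      stop_validation("interaction references unknown protein id: %s", bad)
    }
    if (any(i == j)) stop_validation("self-interaction not allowed")
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  structure(list(proteins = proteins, A = A), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d proteins, %d interactions\n",
              length(x$proteins), sum(x$A) / 2))
  invisible(x)
}

graph_edges <- function(g) {
  idx <- which(upper.tri(g$A) & g$A == 1L, arr.ind = TRUE)
  data.frame(protein_i = g$proteins[idx[, 1L]],
             protein_j = g$proteins[idx[, 2L]],
             stringsAsFactors = FALSE)
}

# elementwise sign with the convention sign(x) = 1 for x > 0, else 0
sign01 <- function(x) (x > 0) + 0L

validate_adjacency <- function(A) {
  if (!is.matrix(A)) stop_validation("adjacency must be a matrix")
  if (nrow(A) != ncol(A)) stop_validation("adjacency must be square")
  if (!all(A %in% c(0, 1))) stop_validation("adjacency must be binary")
  invisible(A)
}

#' Two-hop adjacency
#'
#' Builds the adjacency of the two-hop PPI network as
#' `sign(A %*% t(A))`, where `sign(x)` is 1 for `x > 0` and 0 otherwise.
#' Entry (i, j) is 1 exactly when some node is adjacent to both i and j;
#' in particular the diagonal entry of every node with degree >= 1 is 1
#' (the two-hop network contains self-connections).  Direct edges that also
#' share a common neighbour are retained.
#'
#' @param g A `ppi_graph`.
#' @return A `ppi_hop_graph`: list with `hop = 2`, `proteins`, and `A`.
#' @export
two_hop_adjacency <- function(g) {
  A <- validate_adjacency(g$A)
  assert_square_symmetric(A)
  A2 <- sign01(tcrossprod(A))
  structure(list(hop = 2L, proteins = g$proteins, A = A2),
            class = "ppi_hop_graph")
}

#' k-hop adjacency
#'
#' `k = 1` returns the original adjacency unchanged; `k >= 2` returns
#' `sign(A^k)` (elementwise sign of the k-th matrix power), which for `k = 2`
#' coincides with [two_hop_adjacency()] since A is symmetric.
#'
#' @param g A `ppi_graph`.
#' @param k Hop count, integer >= 1.
#' @return A `ppi_hop_graph` with the given `hop`.
#' @export
k_hop_adjacency <- function(g, k) {
  if (length(k) != 1L || k < 1L || k != round(k)) {
    stop_validation("k must be an integer >= 1")
  }
  A <- validate_adjacency(g$A)
  Ak <- A
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) Ak <- Ak %*% A
    Ak <- sign01(Ak)
  }
  structure(list(hop = as.integer(k), proteins = g$proteins, A = Ak),
            class = "ppi_hop_graph")
}

#' Sample negative (non-interacting) pairs
#'
#' Draws `round(ratio * n_positives)` distinct unordered non-self pairs with
#' `A[i, j] == 0`, uniformly without replacement, as all-zero-label records.
#' Deterministic for a given seed.
#'
#' @param g A `ppi_graph`.
#' @param ratio Positive:negative ratio multiplier (1 gives as many negatives
#'   as positives; 3, 5, 10 give the larger imbalanced sets).
#' @param seed Integer seed.
#' @param vocab Label vocabulary for the all-zero label columns.
#' @return Interaction data.frame with all-zero labels.
#' @export
sample_negatives <- function(g, ratio = 1, seed = 1L, vocab = ppi_label_types()) {
  if (ratio <= 0) stop_validation("ratio must be positive")
  n <- length(g$proteins)
  n_pos <- sum(g$A) / 2
  want <- round(ratio * n_pos)
  nonedge <- which(upper.tri(g$A) & g$A == 0L)
  if (want > length(nonedge)) {
    stop_validation("requested %d negatives but only %d non-edges available",
                    want, length(nonedge))
  }
  pick <- with_seed(seed, sample(nonedge, want))
  i <- row(g$A)[pick]
  j <- col(g$A)[pick]
  cp <- canonical_pairs(g$proteins[i], g$proteins[j])
  out <- data.frame(protein_i = cp$i, protein_j = cp$j, stringsAsFactors = FALSE)
  lab <- matrix(0L, want, length(vocab), dimnames = list(NULL, vocab))
  cbind(out, as.data.frame(lab))
}

#' Write / read an adjacency as an edge-list TSV
#' @param g A `ppi_graph`.
#' @param path Output path.
#' @export
write_edgelist <- function(g, path) {
  e <- graph_edges(g)
  writeLines(paste(e$protein_i, e$protein_j, sep = "\t"), path)
  invisible(path)
}

#' @param proteins Protein id ordering for the adjacency.
#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, proteins) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && any(vapply(parts, length, 1L) != 2L)) {
    stop_validation("edge list rows must have 2 fields")
  }
  pos <- data.frame(protein_i = vapply(parts, `[[`, "", 1L),
                    protein_j = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  build_adjacency(proteins, pos)
}
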