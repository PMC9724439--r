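# Train/test edge splits: uniform random, and BFS/DFS traversal splits that
# emulate prediction for newly discovered proteins by growing the test set
# from a low-degree root.

#' Partition specification
#'
#' @param scheme `"random"`, `"bfs"` or `"dfs"`.
#' @param test_fraction Fraction of positive edges assigned to the test set
#'   (default 0.2); the target edge count is `N = ceiling(test_fraction * |edges|)`.
#' @param degree_threshold Root-degree threshold `t`: traversal roots must
#'   satisfy `1 <= degree(root) < t` (default 5).
#' @param seed Integer seed.
#' @return A `ppi_partition_spec` list.
#' @export
partition_spec <- function(scheme = c("random", "bfs", "dfs"),
                           test_fraction = 0.2,
                           degree_threshold = 5L,
                           seed = 1L) {
  scheme <- match.arg(scheme)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_validation("test_fraction must lie in (0, 1)")
  }
  if (degree_threshold < 1L) stop_validation("degree_threshold must be >= 1")
  structure(list(scheme = scheme, test_fraction = test_fraction,
                 degree_threshold = as.integer(degree_threshold),
                 seed = as.integer(seed)),
            class = "ppi_partition_spec")
}

new_partition <- function(train, test, root, spec) {
  structure(list(train = train, test = test, root = root,
                 scheme = spec$scheme, seed = spec$seed),
            class = "ppi_partition")
}

#' @export
print.ppi_partition <- function(x, ...) {
  cat(sprintf("<ppi_partition> scheme=%s train=%d test=%d root=%s\n",
              x$scheme, nrow(x$train), nrow(x$test), x$root %||% "-"))
  invisible(x)
}

#' Uniform random edge split
#'
#' Samples `ceiling(test_fraction * |edges|)` edges uniformly as the test
#' set; the rest are training edges.
#'
#' @param edges data.frame of positive pairs (`protein_i`, `protein_j`).
#' @param spec A [partition_spec()].
#' @return A `ppi_partition` with disjoint, exhaustive `train` / `test`.
#' @export
split_random <- function(edges, spec = partition_spec("random")) {
  n <- nrow(edges)
  if (n < 1L) stop_validation("empty edge list")
  n_test <- as.integer(ceiling(spec$test_fraction * n))
  pick <- with_seed(spec$seed, sample.int(n, n_test))
  new_partition(train = edges[-pick, , drop = FALSE],
                test = edges[pick, , drop = FALSE],
                root = NULL, spec = spec)
}

#' BFS/DFS traversal edge split
#'
#' Draws a root uniformly (seeded) among nodes with degree in
#' `[1, degree_threshold)`, then grows a visited node set by breadth-first
#' (FIFO) or depth-first (LIFO) traversal, visiting neighbours in ascending
#' protein-index order.  After each visit the test set is every graph edge
#' with both endpoints visited; traversal stops at the first visit where the
#' test set holds at least `N = ceiling(test_fraction * |edges|)` edges.  If
#' a connected component is exhausted first, traversal restarts from a new
#' unvisited eligible root, accumulating the visited set.  All remaining
#' edges (including those with exactly one endpoint visited) are training
#' edges.
#'
#' @param g A `ppi_graph`.
#' @param spec A [partition_spec()] with scheme `"bfs"` or `"dfs"`.
#' @return A `ppi_partition`; `root` holds the first root id.
#' @export
split_traversal <- function(g, spec) {
  if (!spec$scheme %in% c("bfs", "dfs")) {
    stop_validation("split_traversal requires scheme 'bfs' or 'dfs'")
  }
  A <- g$A
  n <- nrow(A)
  deg <- rowSums(A)
  edges <- graph_edges(g)
  n_edges <- nrow(edges)
  if (n_edges < 1L) stop_validation("graph has no edges")
  N <- as.integer(ceiling(spec$test_fraction * n_edges))

  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] == 1L))
  eligible <- which(deg >= 1L & deg < spec$degree_threshold)
  if (!length(eligible)) {
    stop_validation("no eligible root: need a node with degree in [1, %d)",
                    spec$degree_threshold)
  }

  visited <- logical(n)
  test_count <- 0L
  first_root <- NULL
  rng_order <- with_seed(spec$seed, sample(eligible))
  r_ptr <- 1L

  while (test_count < N) {
    # next unvisited eligible root (uniformly ordered by the seeded shuffle)
    while (r_ptr <= length(rng_order) && visited[rng_order[r_ptr]]) {
      r_ptr <- r_ptr + 1L
    }
    if (r_ptr > length(rng_order)) break  # no roots left; keep what we have
    root <- rng_order[r_ptr]
    if (is.null(first_root)) first_root <- root
    frontier <- root  # used as FIFO queue (bfs) or LIFO stack (dfs)
    while (length(frontier) && test_count < N) {
      if (spec$scheme == "bfs") {
        cur <- frontier[1L]
        frontier <- frontier[-1L]
      } else {
        cur <- frontier[length(frontier)]
        frontier <- frontier[-length(frontier)]
      }
      if (visited[cur]) next
      visited[cur] <- TRUE
      # edges newly induced by visiting cur
      test_count <- test_count + sum(visited[nbrs[[cur]]])
      nxt <- nbrs[[cur]][!visited[nbrs[[cur]]]]
      if (length(nxt)) {
        frontier <- if (spec$scheme == "bfs") c(frontier, nxt)
                    else c(frontier, rev(nxt))  # pop in ascending index order
      }
    }
  }

  vi <- match(edges$protein_i, g$proteins)
  vj <- match(edges$protein_j, g$proteins)
  in_test <- visited[vi] & visited[vj]
  new_partition(train = edges[!in_test, , drop = FALSE],
                test = edges[in_test, , drop = FALSE],
                root = g$proteins[first_root], spec = spec)
}

#' Split a set of positive edges under any scheme
#'
#' Dispatches to [split_random()] or [split_traversal()].
#' @param g A `ppi_graph`.
#' @param spec A [partition_spec()].
#' @export
split_edges <- function(g, spec) {
  if (spec$scheme == "random") split_random(graph_edges(g), spec)
  else split_traversal(g, spec)
}
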