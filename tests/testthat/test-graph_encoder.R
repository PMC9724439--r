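test_that("gin_layer aggregates (1+eps) self plus neighbour sum", {
  # isolated node, eps 0, identity MLP: unchanged
  x <- matrix(rnorm(3), 1)
  expect_equal(gin_layer(x, matrix(0, 1, 1)), x)

  # path 1-2-3 with all-ones features: ends double, middle triples
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  X <- matrix(1, 3, 4)
  out <- gin_layer(X, A)
  expect_equal(out, rbind(rep(2, 4), rep(3, 4), rep(2, 4)))

  # nonzero eps scales the self term
  expect_equal(gin_layer(X, A, eps = 0.5)[1, ], rep(2.5, 4))

  # a self-loop contributes the node's own state to the neighbour sum
  As <- A; diag(As) <- 1
  expect_equal(gin_layer(X, As)[1, ], rep(3, 4))

  # permutation equivariance
  set.seed(61)
  A <- random_adjacency(8, 0.4)
  X <- matrix(rnorm(8 * 5), 8, 5)
  mlp <- function(z) tanh(z %*% matrix(seq_len(15) / 15, 5, 3))
  p <- sample(8)
  expect_equal(gin_layer(X, A, 0.3, mlp)[p, ],
               gin_layer(X[p, ], A[p, p], 0.3, mlp))

  # message-passing loop oracle on random graphs
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    A <- random_adjacency(n, 0.3)
    X <- matrix(rnorm(n * 4), n, 4)
    eps <- runif(1, -0.5, 0.5)
    got <- gin_layer(X, A, eps, mlp = function(z) pmax(z, 0))
    for (v in seq_len(n)) {
      agg <- (1 + eps) * X[v, ]
      for (u in which(A[v, ] == 1)) agg <- agg + X[u, ]
      expect_equal(got[v, ], pmax(agg, 0), tolerance = 1e-10)
    }
  }

  expect_error(gin_layer(matrix(0, 3, 2), matrix(0, 2, 2)), "disagree")
})

test_that("encode_branch runs the two-layer MLP over the chosen graph", {
  cfg <- gin_config(hidden = 6, d_emb = 4, input_width = 10)
  set.seed(62)
  params <- ppihop:::init_gin_params(cfg, "gin1")
  X <- matrix(rnorm(5 * 10), 5, 10)

  # zero adjacency, eps 0: every row is the MLP of its own features only,
  # so identical inputs give identical rows
  X2 <- X; X2[2, ] <- X2[1, ]
  E <- encode_branch(X2, matrix(0, 5, 5), cfg, params, branch = 1)
  expect_equal(E[1, ], E[2, ])
  expect_equal(dim(E), c(5L, 4L))

  # explicit message-passing + MLP loop oracle
  A <- random_adjacency(5, 0.5)
  E <- encode_branch(X, A, cfg, params, branch = 1)
  agg <- (1 + params[["gin1.eps"]][1, 1]) * X + A %*% X
  norm01 <- function(h, gm, bt) {
    mu <- colMeans(h); sdv <- sqrt(pmax(colMeans(h^2) - mu^2, 0) + 1e-5)
    sweep(sweep(h, 2, mu), 2, sdv, "/") *
      matrix(gm, nrow(h), length(gm), byrow = TRUE) +
      matrix(bt, nrow(h), length(bt), byrow = TRUE)
  }
  h <- pmax(agg %*% params[["gin1.it1.W1"]] +
              matrix(params[["gin1.it1.b1"]], 5, 6, byrow = TRUE), 0)
  h <- norm01(h, params[["gin1.it1.ng1"]], params[["gin1.it1.nb1"]])
  h <- pmax(h %*% params[["gin1.it1.W2"]] +
              matrix(params[["gin1.it1.b2"]], 5, 4, byrow = TRUE), 0)
  ref <- norm01(h, params[["gin1.it1.ng2"]], params[["gin1.it1.nb2"]])
  expect_equal(E, ref, tolerance = 1e-10)

  # on the two-hop graph of a path, second-order neighbours act first-order:
  # with input width tied to features, branch output for node 1 aggregates
  # node 3 (and itself via the self-connection), not node 2
  P <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  A2 <- two_hop_adjacency(graph_from_A(P))$A
  X3 <- matrix(rnorm(3 * 10), 3, 10)
  agg2 <- (1 + params[["gin1.eps"]][1, 1]) * X3 + A2 %*% X3
  expect_equal(agg2[1, ], (2 + params[["gin1.eps"]][1, 1]) * X3[1, ] + X3[3, ])
})

test_that("fusion is element-wise, commutative summation", {
  set.seed(63)
  E1 <- matrix(rnorm(12), 4, 3)
  E2 <- matrix(rnorm(12), 4, 3)
  expect_equal(fuse_embeddings(E1, matrix(0, 4, 3)), E1)
  expect_equal(fuse_embeddings(E1, E2), fuse_embeddings(E2, E1))
  for (i in 1:4) for (j in 1:3) {
    expect_equal(fuse_embeddings(E1, E2)[i, j], E1[i, j] + E2[i, j])
  }
  expect_error(fuse_embeddings(E1, matrix(0, 3, 3)), "shapes")
})

test_that("node features concatenate sequence and structural blocks to 256", {
  set.seed(64)
  g <- graph_from_A(random_adjacency(9, 0.3))
  S <- matrix(rnorm(9 * 253), 9, 253)
  X <- build_node_features(S, g)
  expect_equal(dim(X), c(9L, 256L))
  expect_equal(X[, 1:253], S)
  # identical sequence features + identical structural role -> identical rows
  iso <- which(rowSums(g$A) == 0)
  if (length(iso) >= 1) expect_true(all(X[iso[1], 254:256] == 0))
  deg <- rowSums(g$A)
  expect_equal(X[, 254], deg / max(1, max(deg)), ignore_attr = TRUE)
  expect_error(build_node_features(matrix(0, 9, 255), g), "too wide")
})

test_that("the branch stack is permutation equivariant and branch-symmetric", {
  cfg <- tiny_model_cfg()
  set.seed(65)
  ds <- tiny_dataset(n = 8, p = 0.4, seed = 65, cfg = cfg)
  m <- ppihop_model(cfg, ds, seed = 4)
  A <- ds$hop_adj[["1"]]
  X <- cbind(matrix(rnorm(8 * cfg$paase$d_seq), 8), ds$struct)

  # same adjacency + shared parameters => the two branches coincide
  p2 <- m$params
  for (nm in grep("^gin1\\.", names(p2), value = TRUE)) {
    p2[[sub("^gin1", "gin2", nm)]] <- p2[[nm]]
  }
  e1 <- encode_branch(X, A, cfg$gin, p2, branch = 1)
  e2 <- encode_branch(X, A, cfg$gin, p2, branch = 2)
  expect_equal(e1, e2)

  # relabeling proteins permutes embedding rows identically
  perm <- sample(8)
  ep <- encode_branch(X[perm, ], A[perm, perm], cfg$gin, m$params, branch = 1)
  expect_equal(ep, encode_branch(X, A, cfg$gin, m$params, branch = 1)[perm, ],
               tolerance = 1e-10)
})
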