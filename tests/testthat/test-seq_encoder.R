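test_that("attention scores are per-head query-key dot products", {
  # orthonormal basis vectors: identity-patterned scores
  q <- k <- diag(1, 4)
  s <- attention_scores(q, k)
  expect_equal(s[[1]], diag(1, 4))

  s1 <- attention_scores(matrix(1:3, 1), matrix(c(2, 0, 1), 1))
  expect_equal(s1[[1]], matrix(5, 1, 1))

  set.seed(51)
  q <- replicate(2, matrix(rnorm(4 * 3), 4, 3), simplify = FALSE)
  k <- replicate(2, matrix(rnorm(4 * 3), 4, 3), simplify = FALSE)
  s <- attention_scores(q, k)
  for (h in 1:2) for (i in 1:4) for (j in 1:4) {
    expect_equal(s[[h]][i, j], sum(q[[h]][i, ] * k[[h]][j, ]))
  }

  expect_error(attention_scores(matrix(0, 2, 3), matrix(0, 2, 4)),
               "width mismatch")
})

test_that("attention output softmax-weights values and projects by W_o", {
  set.seed(52)
  W_o <- matrix(rnorm(2 * 3), 2, 3)
  # single token: softmax weight 1, output = v W_o
  v1 <- matrix(rnorm(2), 1)
  out <- attention_output(matrix(5, 1, 1), v1, list(W_o = W_o, d_k = 4))
  expect_equal(out, v1 %*% W_o)

  # identical tokens produce identical output rows
  v2 <- matrix(rep(c(1, -1), each = 2), 2)
  a2 <- matrix(rnorm(1), 2, 2)
  out2 <- attention_output(a2, v2, list(W_o = W_o, d_k = 4))
  expect_equal(out2[1, ], out2[2, ])

  # 5-token, 2-head random instance against an explicit loop
  q <- replicate(2, matrix(rnorm(5 * 3), 5, 3), simplify = FALSE)
  k <- replicate(2, matrix(rnorm(5 * 3), 5, 3), simplify = FALSE)
  v <- replicate(2, matrix(rnorm(5 * 2), 5, 2), simplify = FALSE)
  Wo <- matrix(rnorm(4 * 6), 4, 6)
  alpha <- attention_scores(q, k)
  got <- attention_output(alpha, v, list(W_o = Wo, d_k = 3))
  ref <- matrix(0, 5, 6)
  for (i in 1:5) {
    zi <- c()
    for (h in 1:2) {
      s <- sapply(1:5, function(j) sum(q[[h]][i, ] * k[[h]][j, ])) / sqrt(3)
      w <- exp(s) / sum(exp(s))
      expect_equal(sum(w), 1, tolerance = 1e-6)
      zi <- c(zi, colSums(w * v[[h]]))
    }
    ref[i, ] <- zi %*% Wo
  }
  expect_equal(got, ref, tolerance = 1e-10)

  # masking: padded keys get zero weight; fully masked input is an error
  m <- c(1, 1, 0, 0, 0)
  gm <- attention_output(alpha, v, list(W_o = Wo, d_k = 3), mask = m)
  ref2 <- attention_output(lapply(alpha, function(a) a[1:2, 1:2]),
                           lapply(v, function(x) x[1:2, , drop = FALSE]),
                           list(W_o = Wo, d_k = 3))
  expect_equal(gm[1:2, ], ref2, tolerance = 1e-10)
  expect_error(attention_output(alpha, v, list(W_o = Wo, d_k = 3),
                                mask = rep(0, 5)), "masked")
})

test_that("attention output is equivariant to a permutation of positions", {
  set.seed(53)
  q <- list(matrix(rnorm(6 * 3), 6, 3))
  k <- list(matrix(rnorm(6 * 3), 6, 3))
  v <- list(matrix(rnorm(6 * 2), 6, 2))
  Wo <- matrix(rnorm(2 * 2), 2, 2)
  par <- list(W_o = Wo, d_k = 3)
  base <- attention_output(attention_scores(q, k), v, par)
  perm <- sample(6)
  permuted <- attention_output(
    attention_scores(list(q[[1]][perm, ]), list(k[[1]][perm, ])),
    list(v[[1]][perm, ]), par
  )
  expect_equal(permuted, base[perm, ], tolerance = 1e-10)
})

test_that("the protein encoder is deterministic, masked and fixed-width", {
  cfg <- paase_config(conv_channels = 6, pool_size = 3, n_heads = 2,
                      d_qk = 4, d_v = 4, d_seq = 9)
  set.seed(54)
  params <- ppihop:::init_paase_params(cfg)
  tab <- aa_embedding_table()
  enc <- encode_sequence(list(id = "a", sequence = "MKVLACDEFGHIK"), tab, 20)
  f1 <- encode_protein(enc$matrix, enc$mask, cfg, params)
  expect_length(f1, 9L)
  # identical sequences -> identical features
  enc2 <- encode_sequence(list(id = "b", sequence = "MKVLACDEFGHIK"), tab, 20)
  expect_equal(encode_protein(enc2$matrix, enc2$mask, cfg, params), f1)
  # appending pure padding leaves the feature unchanged
  enc3 <- encode_sequence(list(id = "c", sequence = "MKVLACDEFGHIK"), tab, 37)
  expect_equal(encode_protein(enc3$matrix, enc3$mask, cfg, params), f1,
               tolerance = 1e-12)
  expect_error(encode_protein(enc$matrix, rep(0, 20), cfg, params),
               "all-padding")
  expect_error(encode_protein(enc$matrix[, 1:12], enc$mask, cfg, params),
               "13 columns")
  # the convolution kernel width is fixed at 3
  expect_error(paase_config(kernel = 5), "fixed at 3")
  expect_equal(paase_config()$kernel, 3L)
})

test_that("a full batch equals per-protein encoding (batching invariance)", {
  cfg <- tiny_model_cfg()
  set.seed(55)
  ds <- tiny_dataset(n = 6, seed = 55, cfg = cfg)
  m <- ppihop_model(cfg, ds, seed = 1)
  tp <- ppihop:::ad_tape()
  S <- ppihop:::paase_forward(tp, ppihop:::ad_leaf(tp, ds$pack$X),
                              ppihop:::wrap_params(tp, m$params),
                              cfg$paase, ds$pack)$value
  tab <- aa_embedding_table()
  for (i in seq_len(nrow(ds$proteins))) {
    enc <- encode_sequence(ds$proteins[i, ], tab, cfg$max_len)
    expect_equal(encode_protein(enc$matrix, enc$mask, cfg$paase, m$params),
                 S[i, ], tolerance = 1e-10)
  }
})
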