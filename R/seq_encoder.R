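# Amino-acid sequence encoder: 1-D convolution over the 13-dim residue
# embeddings, channel normalization, max pooling, a multi-head self-attention
# transformer block with residual connection, global average pooling, and a
# fully connected projection to a fixed-width sequence feature.

#' Sequence-encoder configuration
#'
#' @param conv_channels Output channels of the 1-D convolution (feature_in of
#'   the attention block).
#' @param kernel Convolution kernel size; fixed at 3.
#' @param pool_size Max-pooling window along the sequence.
#' @param n_heads Attention head count `h`.
#' @param d_qk Per-head query/key width (`d_q = d_k`).
#' @param d_v Per-head value width.
#' @param n_layers Number of transformer blocks.
#' @param d_seq Output sequence-feature width.
#' @param norm `"batch"` (per-channel standardization across positions) or
#'   `"layer"` (per-position standardization across channels).
#' @return A `paase_config` list.
#' @export
paase_config <- function(conv_channels = 128L, kernel = 3L, pool_size = 4L,
                         n_heads = 4L, d_qk = 64L, d_v = 64L, n_layers = 1L,
                         d_seq = 253L, norm = c("batch", "layer")) {
  if (kernel != 3L) stop_validation("convolution kernel size is fixed at 3")
  norm <- match.arg(norm)
  stopifnot(conv_channels >= 1L, pool_size >= 1L, n_heads >= 1L,
            d_qk >= 1L, d_v >= 1L, n_layers >= 1L, d_seq >= 1L)
  structure(list(conv_channels = as.integer(conv_channels), kernel = 3L,
                 pool_size = as.integer(pool_size), n_heads = as.integer(n_heads),
                 d_qk = as.integer(d_qk), d_v = as.integer(d_v),
                 n_layers = as.integer(n_layers), d_seq = as.integer(d_seq),
                 norm = norm),
            class = "paase_config")
}

# Glorot-uniform initial weight matrix
glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

# initialize sequence-encoder parameters (flat named list, "seq." prefix);
# caller is responsible for seeding the RNG
init_paase_params <- function(cfg, d_in = 13L) {
  C <- cfg$conv_channels
  p <- list(
    "seq.Wc" = glorot(cfg$kernel * d_in, C),
    "seq.bc" = matrix(0, 1, C),
    "seq.ng1" = matrix(1, 1, C),
    "seq.nb1" = matrix(0, 1, C)
  )
  for (l in seq_len(cfg$n_layers)) {
    for (h in seq_len(cfg$n_heads)) {
      p[[sprintf("seq.l%d.Wq%d", l, h)]] <- glorot(C, cfg$d_qk)
      p[[sprintf("seq.l%d.Wk%d", l, h)]] <- glorot(C, cfg$d_qk)
      p[[sprintf("seq.l%d.Wv%d", l, h)]] <- glorot(C, cfg$d_v)
    }
    p[[sprintf("seq.l%d.Wo", l)]] <- glorot(cfg$n_heads * cfg$d_v, C)
    p[[sprintf("seq.l%d.ng", l)]] <- matrix(1, 1, C)
    p[[sprintf("seq.l%d.nb", l)]] <- matrix(0, 1, C)
  }
  p[["seq.Wf"]] <- glorot(C, cfg$d_seq)
  p[["seq.bf"]] <- matrix(0, 1, cfg$d_seq)
  p
}

# Pack a list of per-protein l x 13 matrices into one row-stacked matrix
# plus the index structures the segmented encoder ops need: im2col gather
# indices for the convolution, per-row segment ids, max-pool block row
# indices, and token block boundaries for the block-diagonal attention.
pack_sequences <- function(encoded, kernel = 3L, pool = 4L) {
  lens <- vapply(encoded, nrow, 1L)
  n <- length(encoded)
  offs <- c(0L, cumsum(lens))
  conv_lens <- lens - kernel + 1L
  i1 <- integer(sum(conv_lens))
  conv_seg <- integer(sum(conv_lens))
  pos <- 0L
  for (i in seq_len(n)) {
    m <- conv_lens[i]
    i1[pos + seq_len(m)] <- offs[i] + seq_len(m)
    conv_seg[pos + seq_len(m)] <- i
    pos <- pos + m
  }
  n_blocks <- as.integer(ceiling(conv_lens / pool))
  B <- sum(n_blocks)
  pool_rows <- matrix(0L, B, pool)
  block_seg <- integer(B)
  cpos <- 0L; b <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n_blocks[i])) {
      b <- b + 1L
      rr <- (cpos + (j - 1L) * pool + 1L):min(cpos + j * pool, cpos + conv_lens[i])
      pool_rows[b, seq_along(rr)] <- rr
      block_seg[b] <- i
    }
    cpos <- cpos + conv_lens[i]
  }
  ends <- cumsum(n_blocks)
  starts <- c(1L, ends[-n] + 1L)
  list(X = do.call(rbind, encoded), n = n, lens = lens,
       i1 = i1, i2 = i1 + 1L, i3 = i1 + 2L, conv_seg = conv_seg,
       pool_rows = pool_rows, block_seg = block_seg,
       starts = starts, ends = ends)
}

# Segmented tape forward over a packed protein batch; returns an n x d_seq
# node (one sequence-feature row per protein).  Per-protein statistics are
# used throughout, so the result is independent of how proteins are batched.
paase_forward <- function(tape, xnode, P, cfg, pack) {
  Xc <- ad_cbind_list(tape, list(ad_gather_rows(tape, xnode, pack$i1),
                                 ad_gather_rows(tape, xnode, pack$i2),
                                 ad_gather_rows(tape, xnode, pack$i3)))
  h <- ad_add(tape, ad_matmul(tape, Xc, P[["seq.Wc"]]), P[["seq.bc"]])
  h <- if (cfg$norm == "batch") {
    ad_segnorm_cols(tape, h, pack$conv_seg, P[["seq.ng1"]], P[["seq.nb1"]])
  } else {
    ad_norm_rows(tape, h, P[["seq.ng1"]], P[["seq.nb1"]])
  }
  h <- ad_relu(tape, h)
  tok <- ad_segmaxpool(tape, h, pack$pool_rows)
  for (l in seq_len(cfg$n_layers)) {
    heads <- vector("list", cfg$n_heads)
    for (hh in seq_len(cfg$n_heads)) {
      Q <- ad_matmul(tape, tok, P[[sprintf("seq.l%d.Wq%d", l, hh)]])
      K <- ad_matmul(tape, tok, P[[sprintf("seq.l%d.Wk%d", l, hh)]])
      V <- ad_matmul(tape, tok, P[[sprintf("seq.l%d.Wv%d", l, hh)]])
      heads[[hh]] <- ad_block_attention(tape, Q, K, V, pack$starts, pack$ends,
                                        1 / sqrt(cfg$d_qk))
    }
    att <- ad_matmul(tape, ad_cbind_list(tape, heads), P[[sprintf("seq.l%d.Wo", l)]])
    tok <- ad_add(tape, tok, att)   # residual connection
    # the transformer block uses per-token layer norm: a channel-standardizing
    # norm here would zero the average pool that follows
    tok <- ad_norm_rows(tape, tok, P[[sprintf("seq.l%d.ng", l)]], P[[sprintf("seq.l%d.nb", l)]])
  }
  pooled <- ad_segmeanpool(tape, tok, pack$block_seg, pack$n)
  ad_add(tape, ad_matmul(tape, pooled, P[["seq.Wf"]]), P[["seq.bf"]])
}

wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

# trim padded rows, enforce a minimum of `kernel` rows by zero padding
trim_encoded <- function(mat, mask, kernel = 3L) {
  l <- sum(mask)
  if (l < 1L) stop_validation("all-padding input: sequence has no valid positions")
  x <- mat[seq_len(l), , drop = FALSE]
  if (l < kernel) x <- rbind(x, matrix(0, kernel - l, ncol(mat)))
  x
}

#' Encode one protein sequence into a fixed-width feature vector
#'
#' Runs the full sequence-encoder forward pass (convolution, normalization,
#' max pooling, multi-head self-attention, average pooling, fully connected
#' projection) on an encoded residue matrix.  Padded positions (mask 0) are
#' removed before the pass and therefore contribute nothing.
#'
#' @param seq_matrix `max_len` x 13 residue-embedding matrix from
#'   [encode_sequence()].
#' @param mask 0/1 length mask of the same length.
#' @param cfg A [paase_config()].
#' @param params Parameter list from the model (see [ppihop_model()]).
#' @return Numeric vector of length `cfg$d_seq`.
#' @export
encode_protein <- function(seq_matrix, mask, cfg, params) {
  if (ncol(seq_matrix) != 13L) stop_validation("sequence matrix must have 13 columns")
  x <- trim_encoded(seq_matrix, mask, cfg$kernel)
  pack <- pack_sequences(list(x), cfg$kernel, cfg$pool_size)
  tape <- ad_tape()
  out <- paase_forward(tape, ad_leaf(tape, pack$X), wrap_params(tape, params),
                       cfg, pack)
  as.vector(out$value)
}

#' Per-head attention scores
#'
#' Raw query-key dot products: `alpha[[h]][i, j] = q[i, ] . k[j, ]` for each
#' head, computed with one matrix product per head.
#'
#' @param q,k Lists of per-head `L x d_k` matrices (a bare matrix is treated
#'   as a single head).
#' @return List of per-head `L x L` score matrices.
#' @export
attention_scores <- function(q, k) {
  if (is.matrix(q)) q <- list(q)
  if (is.matrix(k)) k <- list(k)
  if (length(q) != length(k)) stop_validation("q and k must have the same head count")
  lapply(seq_along(q), function(h) {
    if (ncol(q[[h]]) != ncol(k[[h]])) {
      stop_validation("query/key width mismatch in head %d", h)
    }
    tcrossprod(q[[h]], k[[h]])
  })
}

#' Attention output from scores and values
#'
#' Per head, scales scores by `1/sqrt(d_k)`, masks padded positions to `-Inf`,
#' applies row-wise softmax (rows are convex weights over unmasked positions),
#' and forms the weighted sum of value vectors; head outputs are concatenated
#' and projected by `W_o`.
#'
#' @param alpha List of per-head score matrices from [attention_scores()].
#' @param v List of per-head `L x d_v` value matrices.
#' @param params List with `W_o` (`(h*d_v) x feature_out`) and `d_k`.
#' @param mask Optional 0/1 validity vector of length L.
#' @return `L x feature_out` matrix of token embeddings.
#' @export
attention_output <- function(alpha, v, params, mask = NULL) {
  if (is.matrix(alpha)) alpha <- list(alpha)
  if (is.matrix(v)) v <- list(v)
  if (length(alpha) != length(v)) stop_validation("alpha and v must have the same head count")
  d_k <- params$d_k
  zs <- lapply(seq_along(alpha), function(h) {
    s <- alpha[[h]] / sqrt(d_k)
    if (!is.null(mask)) {
      if (!any(mask == 1)) stop_validation("all positions masked")
      s[, mask == 0] <- -Inf
    }
    w <- exp(s - apply(s, 1L, max))
    w <- w / rowSums(w)
    w %*% v[[h]]
  })
  do.call(cbind, zs) %*% params$W_o
}
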