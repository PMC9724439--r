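test_that("the residue embedding table is 13-dim with a one-hot class block", {
  tab <- aa_embedding_table()
  expect_equal(ncol(tab), 13L)
  onehot <- unclass(tab)[, 6:13]
  expect_true(all(rowSums(onehot) == 1))
  expect_true(all(onehot %in% c(0, 1)))
  # covers canonical residues and the ambiguity codes after the unknown policy
  expect_true(all(c(ppihop:::CANONICAL_AA, "B", "Z", "J", "U", "O", "X") %in%
                    rownames(tab)))
  # ambiguity codes reuse their canonical row; X has its own class
  expect_equal(unclass(tab)["B", ], unclass(tab)["N", ])
  expect_equal(unname(unclass(tab)["X", 13]), 1)
  # deterministic given the seed, and a supplied asset overrides m1
  expect_identical(aa_embedding_table(), aa_embedding_table())
  f <- tempfile(fileext = ".csv")
  co <- data.frame(residue = ppihop:::CANONICAL_AA,
                   matrix(seq_len(100) / 100, 20, 5))
  write.csv(co, f, row.names = FALSE)
  tab2 <- aa_embedding_table(cooccurrence = f)
  expect_equal(unname(unclass(tab2)["A", 1:5]), unname(unlist(co[1, 2:6])))
})

test_that("sequence reading handles TSV and FASTA and validates input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("P1\tMKV", "P2\tACDEF"), f)
  out <- read_sequences(f)
  expect_equal(out$id, c("P1", "P2"))
  expect_equal(out$sequence[1], "MKV")

  writeLines(character(0), f)
  expect_equal(nrow(read_sequences(f, "tsv")), 0L)

  writeLines(c("P1\tMKV", "P1\tAC"), f)
  expect_error(read_sequences(f, "tsv"), "duplicate")
  writeLines(c("P1\tMKV\textra"), f)
  expect_error(read_sequences(f, "tsv"), "line 1")
  writeLines(c("P1\tM1V"), f)
  expect_error(read_sequences(f, "tsv"), "unresolvable")

  # FASTA with a wrapped second record, against an independent line reader
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">Q1 some description", "MKVL", ">Q2", "ACD", "EFG", "HIK"), fa)
  out <- read_sequences(fa)
  lines <- readLines(fa)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[startsWith(lines, ">")]))
  seqs <- tapply(lines, cumsum(startsWith(lines, ">")), function(ch) {
    paste(ch[-1], collapse = "")
  })
  expect_equal(out$id, unname(ids))
  expect_equal(out$sequence, as.character(seqs))
})

test_that("interaction reading merges unordered duplicate pairs by label union", {
  vocab <- ppi_label_types()
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tbinding", "B\tA\treaction"), f)
  out <- read_interactions(f)
  expect_equal(nrow(out), 1L)
  expect_equal(out$protein_i, "A")   # lexicographic canonicalization
  expect_equal(unname(unlist(out[1, vocab])),
               as.integer(vocab %in% c("binding", "reaction")))

  # brute-force grouping oracle on a random row set
  set.seed(21)
  ids <- sprintf("N%d", 1:6)
  rows <- data.frame(a = sample(ids, 40, TRUE), b = sample(ids, 40, TRUE),
                     t = sample(vocab, 40, TRUE), stringsAsFactors = FALSE)
  rows <- rows[rows$a != rows$b, ]
  writeLines(paste(rows$a, rows$b, rows$t, sep = "\t"), f)
  got <- read_interactions(f)
  key <- paste(pmin(rows$a, rows$b), pmax(rows$a, rows$b))
  for (k in unique(key)) {
    expected <- sort(unique(rows$t[key == k]))
    r <- which(paste(got$protein_i, got$protein_j) == k)
    expect_length(r, 1L)
    expect_equal(sort(vocab[unlist(got[r, vocab]) == 1L]), expected)
  }

  writeLines("A\tB\tcatalysis", f)
  expect_equal(sum(unlist(read_interactions(f)[, vocab])), 1L)
  writeLines(paste("A", "B", vocab, sep = "\t"), f)
  expect_equal(unname(unlist(read_interactions(f)[1, vocab])), rep(1L, 7))

  writeLines("A\tB\tsparkling", f)
  expect_error(read_interactions(f), "unknown interaction type")
  writeLines("A\tA\tbinding", f)
  expect_error(read_interactions(f), "self-interaction")
})

test_that("interaction write/read round-trips the canonical pair/label multiset", {
  set.seed(22)
  g <- graph_from_A(random_adjacency(8, 0.4))
  inter <- random_interactions_for(g)
  f <- tempfile(fileext = ".tsv")
  write_interactions(inter, f)
  back <- read_interactions(f)
  o1 <- inter[order(inter$protein_i, inter$protein_j), ]
  o2 <- back[order(back$protein_i, back$protein_j), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
})

test_that("sequence encoding pads, truncates and masks correctly", {
  tab <- aa_embedding_table()
  enc <- encode_sequence(list(id = "p", sequence = "M"), tab, max_len = 3)
  expect_equal(dim(enc$matrix), c(3L, 13L))
  expect_equal(enc$matrix[1, ], unname(unclass(tab)["M", ]))
  expect_true(all(enc$matrix[2:3, ] == 0))
  expect_equal(enc$mask, c(1L, 0L, 0L))

  # truncation keeps the first max_len residues (per-residue lookup oracle)
  enc5 <- encode_sequence(list(id = "p", sequence = "MKVAC"), tab, max_len = 3)
  ref <- t(vapply(c("M", "K", "V"), function(ch) unclass(tab)[ch, ], numeric(13)))
  expect_equal(enc5$matrix, unname(ref))
  expect_equal(enc5$length, 5L)
  expect_equal(sum(enc5$mask), 3L)

  expect_error(encode_sequence(list(id = "p", sequence = "M*V"), tab, 5),
               "not covered")
  expect_error(encode_sequence(list(id = "p", sequence = "MKV"), tab, 0),
               "max_len")
})
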