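# Sequence and interaction-table I/O, the per-residue embedding table, and
# the fixed interaction-type vocabulary.

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# physicochemical classes (electrostatic/hydrophobic grouping): seven classes
# of canonical residues plus an eighth "unspecified" class used only by X
AA_CLASS <- c(
  A = 1L, G = 1L, V = 1L,
  I = 2L, L = 2L, F = 2L, P = 2L,
  Y = 3L, M = 3L, T = 3L, S = 3L,
  H = 4L, N = 4L, Q = 4L, W = 4L,
  R = 5L, K = 5L,
  D = 6L, E = 6L,
  C = 7L
)

# ambiguity codes resolve to the canonical residue they most plausibly stand
# for (B = Asn/Asp, Z = Gln/Glu, J = Leu/Ile, U = selenocysteine, O = pyrrolysine)
AA_AMBIGUOUS <- c(B = "N", Z = "Q", J = "L", U = "C", O = "K")

#' Interaction-type vocabulary
#'
#' The seven STRING interaction ("mode") types used as the multi-label class
#' vocabulary, in fixed order: post-translational modification, catalysis,
#' reaction, activation, expression, binding, inhibition.  The order is part
#' of the model contract and is serialized with trained models.
#'
#' @return Character vector of length 7.
#' @export
ppi_label_types <- function() {
  c("ptmod", "catalysis", "reaction", "activation", "expression",
    "binding", "inhibition")
}

#' Per-residue 13-dimensional embedding table
#'
#' Each amino-acid letter maps to a 13-dimensional vector `[m1, m2]`: a 5-dim
#' co-occurrence component `m1` and an 8-dim one-hot physicochemical-class
#' indicator `m2`.  The published co-occurrence values live in an external
#' asset; when a `cooccurrence` CSV (column `residue` plus five numeric
#' columns) is supplied its rows are used for `m1`, otherwise a deterministic
#' seeded random 5-dim vector per canonical residue is substituted — the
#' downstream encoder only requires fixed, distinct 13-dim inputs.
#'
#' Ambiguity codes (B, Z, J, U, O) reuse the row of their closest canonical
#' residue; X takes the mean co-occurrence vector and the dedicated eighth
#' one-hot class.
#'
#' @param cooccurrence Optional path to a CSV asset with the 5-dim component.
#' @param seed Seed for the substitute co-occurrence vectors.
#' @return A 26 x 13 numeric matrix with residue-letter rownames, class
#'   `aa_embedding_table`.
#' @export
aa_embedding_table <- function(cooccurrence = NULL, seed = 101L) {
  m1 <- if (!is.null(cooccurrence)) {
    df <- utils::read.csv(cooccurrence, stringsAsFactors = FALSE)
    if (ncol(df) != 6L) stop_validation("co-occurrence asset must have residue + 5 numeric columns")
    m <- as.matrix(df[, -1L])
    rownames(m) <- toupper(df[[1L]])
    missing <- setdiff(CANONICAL_AA, rownames(m))
    if (length(missing)) stop_validation("co-occurrence asset misses residues: %s",
                                         paste(missing, collapse = ", "))
    m[CANONICAL_AA, , drop = FALSE]
  } else {
    with_seed(seed, {
      m <- matrix(stats::rnorm(20L * 5L, sd = 0.5), 20L, 5L)
      rownames(m) <- CANONICAL_AA
      m
    })
  }
  onehot <- matrix(0, 20L, 8L, dimnames = list(CANONICAL_AA, NULL))
  onehot[cbind(seq_len(20L), AA_CLASS[CANONICAL_AA])] <- 1
  tab <- cbind(m1, onehot)

  amb <- do.call(rbind, lapply(AA_AMBIGUOUS, function(target) tab[target, ]))
  rownames(amb) <- names(AA_AMBIGUOUS)
  x_row <- c(colMeans(m1), c(rep(0, 7L), 1))
  tab <- rbind(tab, amb, X = x_row)
  colnames(tab) <- c(paste0("cooc", 1:5), paste0("class", 1:8))
  class(tab) <- c("aa_embedding_table", class(tab))
  tab
}

#' Read protein sequences
#'
#' Reads a protein-sequence table from FASTA (multi-line records, `>` headers;
#' parsed with [Biostrings::readAAStringSet()]) or a two-column TSV
#' (`id<TAB>sequence`, no header).  Order of first appearance is preserved and
#' duplicate identifiers are rejected.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension / leading `>`), `"fasta"`, or `"tsv"`.
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) "fasta"
              else if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv"
              else if (length(ln <- readLines(path, n = 1L)) && startsWith(ln, ">")) "fasta"
              else "tsv"
  }
  if (format == "fasta") {
    set <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    lines <- readLines(path)
    keep <- nzchar(lines)
    lines <- lines[keep]
    if (!length(lines)) {
      return(data.frame(id = character(), sequence = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad)) {
      stop_validation("malformed sequence TSV at line %d: expected 2 tab-separated fields",
                      which(keep)[bad[1L]])
    }
    ids <- vapply(parts, `[[`, "", 1L)
    seqs <- vapply(parts, `[[`, "", 2L)
  }
  if (anyDuplicated(ids)) {
    stop_validation("duplicate protein id: %s", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop_validation("empty sequence for id %s", ids[!nzchar(seqs)][1L])
  check_residues(seqs, ids)
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

check_residues <- function(seqs, ids) {
  allowed <- c(CANONICAL_AA, names(AA_AMBIGUOUS), "X")
  letters_seen <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  bad <- setdiff(letters_seen, allowed)
  if (length(bad)) {
    hit <- grepl(paste0("[", paste(bad, collapse = ""), "]"), seqs)
    stop_validation("unresolvable residue(s) %s in sequence %s",
                    paste(bad, collapse = ","), ids[hit][1L])
  }
  invisible(NULL)
}

#' Write protein sequences
#'
#' @param proteins data.frame with `id` and `sequence`.
#' @param path Output file.
#' @param format `"tsv"` or `"fasta"`.
#' @export
write_sequences <- function(proteins, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(paste(proteins$id, proteins$sequence, sep = "\t"), path)
  } else {
    set <- Biostrings::AAStringSet(proteins$sequence)
    names(set) <- proteins$id
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

#' Read a typed interaction table
#'
#' Reads a 3-column TSV (`protein_i<TAB>protein_j<TAB>type`) of typed,
#' undirected interactions.  Rows sharing the same unordered pair are merged
#' into a single record whose label is the multi-hot union of the row types;
#' pair order is canonicalized lexicographically.
#'
#' @param path Input TSV.
#' @param vocab Ordered label vocabulary (default [ppi_label_types()]).
#' @return A data.frame with columns `protein_i`, `protein_j` and one 0/1
#'   column per vocabulary entry.
#' @export
read_interactions <- function(path, vocab = ppi_label_types()) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines))
  if (!length(keep)) return(empty_interactions(vocab))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad)) {
    stop_validation("malformed interaction TSV at line %d: expected 3 tab-separated fields",
                    keep[bad[1L]])
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  ty <- vapply(parts, `[[`, "", 3L)
  if (any(a == b)) {
    stop_validation("self-interaction pair at line %d (%s)",
                    keep[which(a == b)[1L]], a[a == b][1L])
  }
  unk <- !(ty %in% vocab)
  if (any(unk)) {
    stop_validation("unknown interaction type '%s' at line %d",
                    ty[unk][1L], keep[which(unk)[1L]])
  }
  cp <- canonical_pairs(a, b)
  key <- pair_key(cp$i, cp$j)
  ukey <- unique(key)
  lab <- matrix(0L, length(ukey), length(vocab), dimnames = list(NULL, vocab))
  lab[cbind(match(key, ukey), match(ty, vocab))] <- 1L
  first <- match(ukey, key)
  out <- data.frame(protein_i = cp$i[first], protein_j = cp$j[first],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(lab))
}

empty_interactions <- function(vocab = ppi_label_types()) {
  out <- data.frame(protein_i = character(), protein_j = character(),
                    stringsAsFactors = FALSE)
  for (v in vocab) out[[v]] <- integer()
  out
}

#' Write a typed interaction table
#'
#' Inverse of [read_interactions()]: expands each multi-hot record into one
#' TSV row per set label type.
#' @param interactions Interaction data.frame.
#' @param path Output TSV.
#' @param vocab Label vocabulary.
#' @export
write_interactions <- function(interactions, path, vocab = ppi_label_types()) {
  lab <- interaction_labels(interactions, vocab)
  rows <- character(0)
  for (r in seq_len(nrow(interactions))) {
    types <- vocab[lab[r, ] == 1L]
    rows <- c(rows, paste(interactions$protein_i[r], interactions$protein_j[r],
                          types, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

# extract the n x 7 label matrix from an interaction data.frame
interaction_labels <- function(interactions, vocab = ppi_label_types()) {
  missing <- setdiff(vocab, names(interactions))
  if (length(missing)) stop_validation("interaction table misses label column(s): %s",
                                       paste(missing, collapse = ", "))
  as.matrix(interactions[, vocab, drop = FALSE])
}

#' Encode a protein sequence as a padded residue-embedding matrix
#'
#' Looks up each residue in the embedding table, truncates at `max_len` and
#' zero-pads shorter sequences, returning the matrix together with a 0/1
#' length mask.
#'
#' @param rec A protein record: list or one-row data.frame with `id`,
#'   `sequence`.
#' @param table An [aa_embedding_table()].
#' @param max_len Fixed output length (rows), >= 1.
#' @return List with `matrix` (`max_len` x 13), `mask` (length `max_len`),
#'   and `length` (the untruncated sequence length).
#' @export
encode_sequence <- function(rec, table = aa_embedding_table(), max_len = 512L) {
  if (max_len < 1L) stop_validation("max_len must be >= 1")
  seq <- toupper(rec$sequence)
  if (!nzchar(seq)) stop_validation("empty sequence for id %s", rec$id %||% "?")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  miss <- setdiff(chars, rownames(table))
  if (length(miss)) {
    stop_validation("residue '%s' in %s not covered by the embedding table",
                    miss[1L], rec$id %||% "?")
  }
  l <- min(length(chars), max_len)
  out <- matrix(0, max_len, ncol(table))
  out[seq_len(l), ] <- unclass(table)[chars[seq_len(l)], , drop = FALSE]
  mask <- c(rep(1L, l), rep(0L, max_len - l))
  list(matrix = out, mask = mask, length = length(chars))
}
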