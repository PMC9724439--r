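`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded internals never perturb user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a secondary seed from a user seed; stays below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_binary_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop_validation("%s must be a matrix", name)
  if (!all(x %in% c(0, 1))) stop_validation("%s must be binary (0/1)", name)
  invisible(x)
}

assert_square_symmetric <- function(A, name = "A") {
  if (nrow(A) != ncol(A)) stop_validation("%s must be square", name)
  if (!isTRUE(all.equal(A, t(A)))) stop_validation("%s must be symmetric", name)
  invisible(A)
}

# broadcast a length-d vector across m rows
bcast_rows <- function(v, m) matrix(v, nrow = m, ncol = length(v), byrow = TRUE)

# canonical unordered pair ordering (lexicographic on ids)
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(i = a, j = b)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")
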