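# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.  `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Row weights for reading an input tuple as a binary number, first input =
# most significant bit: k inputs -> c(2^(k-1), ..., 2, 1).
bit_weights <- function(k) {
  if (k == 0L) return(integer(0))
  2L^((k - 1L):0L)
}

# Integer 0..2^k-1 -> binary vector of length k, MSB first.
int_to_bits <- function(x, k) {
  if (k == 0L) return(integer(0))
  as.integer(intToBits(x))[k:1L]
}

# Compact string key for a binary state vector.
state_key <- function(state) paste(state, collapse = "")

key_to_state <- function(key) as.integer(strsplit(key, "", fixed = TRUE)[[1L]])

# Canonical string for a directed edge.
edge_id <- function(source, target) paste(source, target, sep = "\r")

edge_tbl <- function(source = character(), target = character()) {
  tibble::tibble(source = as.character(source), target = as.character(target))
}

# Sort an edge table lexicographically (source, then target) - the canonical
# deterministic iteration order used throughout.
sort_edges <- function(edges) {
  edges[order(edges$source, edges$target, method = "radix"), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
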