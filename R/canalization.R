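# Canalizing-function detection and redundant-link identification via exact
# two-level logic minimization (Quine-McCluskey).

#' Canalizing inputs of a logic table
#'
#' An input u canalizes a Boolean function with value a forcing output b
#' when the output equals b on every row with u = a, regardless of the
#' other inputs.  All such triples (input, canalizing value, forced output)
#' are returned, verified exhaustively over the table.  For a constant
#' function every input trivially canalizes with either value.
#'
#' @param table A [logic_table()] with at least one input.
#' @return A tibble with columns `input`, `value` and `output`; zero rows
#'   for non-canalizing functions such as XOR.
#' @examples
#' canalizing_inputs(logic_table("B", c("X", "Y"), c(0, 1, 1, 1))) # OR
#' @export
canalizing_inputs <- function(table) {
  stopifnot(inherits(table, "logic_table"))
  k <- length(table$inputs)
  if (k < 1L) stop("table has no inputs", call. = FALSE)
  rows <- seq_len(2L^k) - 1L
  out <- list()
  for (pos in seq_len(k)) {
    bit <- bitwAnd(rows %/% 2L^(k - pos), 1L)
    for (a in 0:1) {
      ys <- table$outputs[bit == a]
      if (length(unique(ys)) == 1L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          input = table$inputs[pos], value = a, output = ys[1L])
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(input = character(), value = integer(),
                          output = integer()))
  }
  dplyr::bind_rows(out)
}

# --- Quine-McCluskey --------------------------------------------------------

# Prime implicants of the function whose ON-set is `minterms` (integers in
# 0..2^k-1) over k variables.  An implicant is a pair (bits, mask): `mask`
# has 1s at "don't care" positions, `bits` the fixed values elsewhere
# (positions counted from the MSB-first row encoding).
qm_prime_implicants <- function(minterms, k) {
  if (length(minterms) == 0L) {
    return(list())
  }
  if (length(minterms) == 2L^k) {
    return(list(list(bits = 0L, mask = 2L^k - 1L)))
  }
  current <- unique(lapply(sort(minterms), function(m) {
    list(bits = as.integer(m), mask = 0L)
  }))
  primes <- list()
  while (length(current) > 0L) {
    combined <- rep(FALSE, length(current))
    nxt <- list()
    seen <- character(0)
    masks <- vapply(current, function(x) x$mask, integer(1))
    bits <- vapply(current, function(x) x$bits, integer(1))
    ones <- vapply(bits, function(b) sum(int_to_bits(b, k)), integer(1))
    for (i in seq_along(current)) {
      for (j in seq_along(current)) {
        if (j <= i || masks[i] != masks[j]) next
        if (abs(ones[i] - ones[j]) != 1L) next
        d <- bitwXor(bits[i], bits[j])
        if (sum(int_to_bits(d, k)) != 1L) next
        combined[i] <- combined[j] <- TRUE
        nb <- bitwAnd(bits[i], bitwNot(d))
        nm <- bitwOr(masks[i], d)
        key <- paste(nb, nm)
        if (!key %in% seen) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <- list(bits = nb, mask = nm)
        }
      }
    }
    primes <- c(primes, current[!combined])
    current <- nxt
  }
  primes
}

implicant_covers <- function(imp, minterm) {
  bitwAnd(bitwXor(imp$bits, minterm), bitwNot(imp$mask)) == 0L
}

# Exact minimum cover: essential primes first, then branch-and-bound over
# the rest (table widths in signaling models are small).
qm_minimal_cover <- function(primes, minterms) {
  if (length(minterms) == 0L) return(list())
  cover <- vapply(primes, function(p) {
    vapply(minterms, function(m) implicant_covers(p, m), logical(1))
  }, logical(length(minterms)))
  cover <- matrix(cover, nrow = length(minterms))
  chosen <- integer(0)
  uncovered <- rep(TRUE, length(minterms))
  repeat {
    ess <- which(uncovered)[rowSums(cover[uncovered, , drop = FALSE]) == 1]
    if (length(ess) == 0L) break
    for (m in ess) {
      p <- which(cover[m, ])[1L]
      if (!p %in% chosen) chosen <- c(chosen, p)
    }
    uncovered <- uncovered & !apply(cover[, chosen, drop = FALSE], 1, any)
    if (!any(uncovered)) break
  }
  if (any(uncovered)) {
    rest <- setdiff(seq_along(primes), chosen)
    need <- which(uncovered)
    best <- NULL
    for (size in seq_along(rest)) {
      combos <- combn(rest, size, simplify = FALSE)
      for (cb in combos) {
        if (all(apply(cover[need, cb, drop = FALSE], 1, any))) {
          best <- cb
          break
        }
      }
      if (!is.null(best)) break
    }
    chosen <- c(chosen, best)
  }
  primes[sort(chosen)]
}

# Variable positions (1-based, MSB first) used by any implicant in a cover.
cover_literals <- function(cover, k) {
  used <- logical(k)
  for (imp in cover) {
    free <- int_to_bits(imp$mask, k)
    used <- used | (free == 0L)
  }
  which(used)
}

#' Redundant inputs of a logic table
#'
#' An input is redundant when it appears in no prime implicant of the
#' minimal two-level cover of the function nor of its complement, computed
#' by exact Quine-McCluskey minimization.  Non-essential (fictitious)
#' inputs, whose two reduced tables coincide, are always redundant.
#'
#' @param table A [logic_table()].
#' @param max_width Minimization cap on the number of inputs (default 16).
#' @return Character vector of redundant input ids.
#' @export
redundant_inputs <- function(table, max_width = 16L) {
  stopifnot(inherits(table, "logic_table"))
  k <- length(table$inputs)
  if (k == 0L) return(character(0))
  if (k > max_width) {
    stop("table width ", k, " above minimization cap ", max_width,
         call. = FALSE)
  }
  on_rows <- which(table$outputs == 1L) - 1L
  off_rows <- which(table$outputs == 0L) - 1L
  used <- union(
    cover_literals(qm_minimal_cover(qm_prime_implicants(on_rows, k),
                                    on_rows), k),
    cover_literals(qm_minimal_cover(qm_prime_implicants(off_rows, k),
                                    off_rows), k)
  )
  table$inputs[setdiff(seq_len(k), used)]
}

#' Canalization profile of a node
#'
#' @inheritParams redundant_inputs
#' @return A list with `node`, `canalizing` (tibble from
#'   [canalizing_inputs()]) and `redundant` (character vector from
#'   [redundant_inputs()]).
#' @export
canalization_profile <- function(table, max_width = 16L) {
  list(node = table$target,
       canalizing = canalizing_inputs(table),
       redundant = redundant_inputs(table, max_width))
}

#' Redundant links of a network
#'
#' The edge (u, v) is redundant when u is a redundant input of v's logic
#' table (see [redundant_inputs()]).  This is a purely local property of
#' each table: it does not depend on clamps, dynamics or seeds, which is
#' precisely how it differs from robust-neighbor membership.
#'
#' @param net A [boolean_network()].
#' @param max_width Minimization cap per table.
#' @return A tibble of redundant edges (`source`, `target`).
#' @export
redundant_links <- function(net, max_width = 16L) {
  stopifnot(inherits(net, "boolean_network"))
  rows <- lapply(net$tables, function(tb) {
    red <- redundant_inputs(tb, max_width)
    if (length(red)) edge_tbl(red, rep(tb$target, length(red)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(edge_tbl())
  sort_edges(out)
}

#' Overlap of redundant links with a decomposition
#'
#' Intersects the locally redundant edge set with the dynamically derived
#' evolvable core and robust neighbor.
#'
#' @inheritParams node_scores
#' @param max_width Minimization cap per table.
#' @return A tibble with `n_redundant`, `n_redundant_core` and
#'   `n_redundant_neighbor`.
#' @export
compare_redundant_vs_decomposition <- function(net, decomposition,
                                               max_width = 16L) {
  stopifnot(inherits(decomposition, "bn_decomposition"))
  red <- redundant_links(net, max_width)
  net_ids <- edge_id(decomposition$provenance$source,
                     decomposition$provenance$target)
  red_ids <- edge_id(red$source, red$target)
  if (length(bad <- setdiff(red_ids, net_ids))) {
    stop("redundant edge outside the decomposed edge universe",
         call. = FALSE)
  }
  core_ids <- edge_id(decomposition$core_edges$source,
                      decomposition$core_edges$target)
  tibble::tibble(
    n_redundant = length(red_ids),
    n_redundant_core = sum(red_ids %in% core_ids),
    n_redundant_neighbor = sum(!red_ids %in% core_ids)
  )
}
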