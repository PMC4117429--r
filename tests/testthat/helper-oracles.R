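# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the package's compiled-network code path.

# Naive synchronous step working straight off the logic tables.
naive_step <- function(net, state) {
  names(state) <- net$nodes
  nxt <- state
  for (tb in net$tables) {
    k <- length(tb$inputs)
    row <- if (k == 0) 0 else {
      bits <- state[tb$inputs]
      sum(bits * 2^((k - 1):0))
    }
    nxt[tb$target] <- tb$outputs[row + 1]
  }
  for (v in net$inputs) nxt[v] <- net$clamp[[v]]
  unname(nxt)
}

# One asynchronous sweep in an explicit node order.
naive_async_sweep <- function(net, state, order_idx) {
  names(state) <- net$nodes
  st <- state
  for (v in net$inputs) st[v] <- net$clamp[[v]]
  for (j in order_idx) {
    v <- net$nodes[j]
    tb <- net$tables[[v]]
    if (is.null(tb)) next
    k <- length(tb$inputs)
    row <- if (k == 0) 0 else sum(st[tb$inputs] * 2^((k - 1):0))
    st[v] <- tb$outputs[row + 1]
  }
  unname(st)
}

# All states reachable in one async sweep, over every node permutation.
oracle_async_reachable <- function(net, state) {
  n <- length(net$nodes)
  perms <- gtools_permutations(n)
  keys <- unique(vapply(seq_len(nrow(perms)), function(i) {
    paste(naive_async_sweep(net, state, perms[i, ]), collapse = "")
  }, character(1)))
  sort(keys)
}

# All permutations of 1..n (n small), without external packages.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# Brute-force attractor landscape: follows naive_step from every free
# assignment.  Attractors are identified by the SET of states on the cycle
# (rotation-free), returned as a sorted-key signature with basin counts.
oracle_attractors <- function(net) {
  free <- setdiff(net$nodes, net$inputs)
  f <- length(free)
  basins <- list()
  for (r in 0:(2^f - 1)) {
    bits <- as.integer(intToBits(r))[f:1]
    st <- integer(length(net$nodes))
    names(st) <- net$nodes
    for (v in net$inputs) st[v] <- net$clamp[[v]]
    st[free] <- bits
    st <- unname(st)
    seen <- character(0)
    repeat {
      key <- paste(st, collapse = "")
      if (key %in% seen) {
        cyc <- seen[which(seen == key):length(seen)]
        sig <- paste(sort(cyc), collapse = "|")
        basins[[sig]] <- (if (is.null(basins[[sig]])) 0 else basins[[sig]]) + 1
        break
      }
      seen <- c(seen, key)
      st <- naive_step(net, st)
    }
  }
  basins[order(names(basins))]
}

# Landscape object -> the oracle's rotation-free signature/count mapping.
landscape_signature <- function(land) {
  sig <- lapply(land$attractors, function(a) a$basin_count)
  names(sig) <- vapply(land$attractors, function(a) {
    paste(sort(a$keys), collapse = "|")
  }, character(1))
  sig[order(names(sig))]
}

# Exhaustive count of simple directed cycles of exactly k distinct nodes.
oracle_cycle_count <- function(edges, nodes, k) {
  has <- function(u, v) any(edges$source == u & edges$target == v)
  if (k == 1) return(sum(vapply(nodes, function(v) has(v, v), logical(1))))
  cnt <- 0
  if (k == 2) {
    pairs <- if (length(nodes) >= 2) combn(nodes, 2, simplify = FALSE) else list()
    for (p in pairs) if (has(p[1], p[2]) && has(p[2], p[1])) cnt <- cnt + 1
    return(cnt)
  }
  trips <- if (length(nodes) >= 3) combn(nodes, 3, simplify = FALSE) else list()
  for (tset in trips) {
    perms <- list(c(1, 2, 3), c(1, 3, 2))
    for (pm in perms) {
      a <- tset[pm[1]]; b <- tset[pm[2]]; d <- tset[pm[3]]
      if (has(a, b) && has(b, d) && has(d, a)) cnt <- cnt + 1
    }
  }
  cnt
}

# All free-node assignments of a network, as full states.
all_free_states <- function(net) {
  free <- setdiff(net$nodes, net$inputs)
  f <- length(free)
  lapply(0:(2^f - 1), function(r) {
    bits <- as.integer(intToBits(r))[f:1]
    st <- integer(length(net$nodes))
    names(st) <- net$nodes
    for (v in net$inputs) st[v] <- net$clamp[[v]]
    st[free] <- bits
    unname(st)
  })
}

# A small random digraph as an edge tibble (no duplicate edges).
random_digraph <- function(n, p, seed, self_loops = TRUE) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  if (!self_loops) pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  list(edges = tibble::as_tibble(pairs[keep, ]), nodes = nodes)
}
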