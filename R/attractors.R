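# Attractor-landscape estimation: sampled (Monte Carlo over random initial
# states) and exact (full state-graph traversal for small models).

# Canonical form of a cyclic state sequence: the rotation whose sequence of
# state keys is lexicographically minimal.  Fixed points are 1-cycles.
canonical_cycle <- function(states) {
  keys <- vapply(states, state_key, character(1))
  L <- length(keys)
  if (L == 1L) {
    return(list(states = states, keys = keys, id = keys))
  }
  best <- NULL
  best_concat <- NULL
  for (r in which(keys == min(keys))) {
    rot <- c(r:L, seq_len(r - 1L))
    concat <- paste(keys[rot], collapse = "|")
    if (is.null(best_concat) || concat < best_concat) {
      best_concat <- concat
      best <- rot
    }
  }
  list(states = states[best], keys = keys[best], id = best_concat)
}

new_attractor <- function(canon, basin_count, sample_size) {
  structure(
    list(states = canon$states, keys = canon$keys, id = canon$id,
         basin_count = basin_count,
         basin_fraction = basin_count / sample_size),
    class = "bn_attractor"
  )
}

#' @export
print.bn_attractor <- function(x, ...) {
  kind <- if (length(x$states) == 1L) "fixed point" else
    paste0("limit cycle of length ", length(x$states))
  cat("<bn_attractor> ", kind, ", basin ", x$basin_count, " (",
      format(100 * x$basin_fraction, digits = 3), "%)\n", sep = "")
  for (k in x$keys) cat("  ", k, "\n", sep = "")
  invisible(x)
}

#' @export
format.bn_attractor <- function(x, ...) x$id

new_landscape <- function(attractors, sample_size, seed, mode, nodes) {
  counts <- vapply(attractors, function(a) a$basin_count, numeric(1))
  ids <- vapply(attractors, function(a) a$id, character(1))
  ord <- order(-counts, ids, method = "radix")
  attractors <- attractors[ord]
  primary_index <- 1L # max count, ties broken by lexicographically least id
  structure(
    list(attractors = attractors, sample_size = sample_size, seed = seed,
         primary_index = primary_index, mode = mode, nodes = nodes),
    class = "bn_landscape"
  )
}

#' @export
print.bn_landscape <- function(x, ...) {
  cat("<bn_landscape> ", length(x$attractors), " attractor(s) from ",
      x$sample_size, " initial states (", x$mode, ")\n", sep = "")
  print(tidy(x), n = 10)
  invisible(x)
}

#' Estimate the attractor landscape from sampled initial states
#'
#' Draws initial states uniformly at random over the free-node assignments
#' (clamped inputs held fixed), runs each to its attractor with
#' [run_to_cycle()], and accumulates basin counts per attractor, where two
#' attractors are identified exactly when their canonical cyclic state
#' sequences coincide.  With `init_states` supplied the given states are
#' used instead of random draws (e.g. every free assignment, for exhaustive
#' coverage, or the identical sample reused across networks).
#'
#' @param net A [boolean_network()].
#' @param n_samples Number of random initial states (ignored when
#'   `init_states` is given).
#' @param seed Integer seed making the sample reproducible.
#' @param init_states Optional list of full initial states.
#' @param max_steps Passed to [run_to_cycle()].
#' @return A `bn_landscape`: attractors sorted by decreasing basin count
#'   (ties by canonical sequence), with `primary_index` marking the primary
#'   attractor, `sample_size`, `seed` and `mode = "sampled"`.
#' @examples
#' land <- find_attractors(fixture_network("TRIAD"), n_samples = 100, seed = 1)
#' tidy(land)
#' @export
find_attractors <- function(net, n_samples = 10000L, seed = NULL,
                            init_states = NULL, max_steps = 10000L) {
  stopifnot(inherits(net, "boolean_network"))
  cn <- compile_network(net)
  f <- length(cn$free_idx)
  if (f < 1L) stop("network has no free nodes", call. = FALSE)
  states <- if (!is.null(init_states)) {
    lapply(init_states, check_state, net = net)
  } else {
    stopifnot(n_samples >= 1L)
    with_seed(seed, lapply(seq_len(n_samples), function(i) {
      make_state(cn, as.integer(runif(f) < 0.5))
    }))
  }
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  canons <- new.env(parent = emptyenv(), hash = TRUE)
  for (st in states) {
    tr <- tryCatch(compiled_run_to_cycle(cn, st, max_steps),
      error = function(e) {
        stop("horizon exceeded from initial state ", state_key(st),
             call. = FALSE)
      })
    canon <- canonical_cycle(tr$cycle)
    counts[[canon$id]] <- (counts[[canon$id]] %||% 0L) + 1L
    if (is.null(canons[[canon$id]])) canons[[canon$id]] <- canon
  }
  ids <- ls(counts)
  attractors <- lapply(ids, function(id) {
    new_attractor(canons[[id]], counts[[id]], length(states))
  })
  new_landscape(attractors, length(states), seed, "sampled", net$nodes)
}

#' Exact attractor landscape by full state-graph traversal
#'
#' Enumerates every free-node assignment, follows each trajectory with path
#' memoization, and returns the exact attractor set with exact basin sizes.
#' Serves as the brute-force oracle for [find_attractors()] in the regime
#' where the `2^f` states are enumerable.
#'
#' @inheritParams find_attractors
#' @param max_free Refuse networks with more free nodes than this cap
#'   (default 20).
#' @return A `bn_landscape` with `mode = "exact"` and
#'   `sample_size = 2^f`.
#' @export
enumerate_attractors <- function(net, max_free = 20L) {
  stopifnot(inherits(net, "boolean_network"))
  cn <- compile_network(net)
  f <- length(cn$free_idx)
  if (f < 1L) stop("network has no free nodes", call. = FALSE)
  if (f > max_free) {
    stop("network has ", f, " free nodes; cap is ", max_free, call. = FALSE)
  }
  assign_to <- new.env(parent = emptyenv(), hash = TRUE) # key -> attractor id
  canons <- list()
  counts <- integer(0)
  for (r in seq_len(2L^f) - 1L) {
    st <- make_state(cn, int_to_bits(r, f))
    path_keys <- character(0)
    path_pos <- new.env(parent = emptyenv(), hash = TRUE)
    aid <- NA_integer_
    repeat {
      key <- state_key(st)
      known <- assign_to[[key]]
      if (!is.null(known)) { aid <- known; break }
      p <- path_pos[[key]]
      if (!is.null(p)) {
        # new cycle discovered on this path
        cyc_keys <- path_keys[p:length(path_keys)]
        canon <- canonical_cycle(lapply(cyc_keys, key_to_state))
        canons[[length(canons) + 1L]] <- canon
        counts <- c(counts, 0L)
        aid <- length(canons)
        break
      }
      path_keys <- c(path_keys, key)
      path_pos[[key]] <- length(path_keys)
      st <- compiled_step(cn, st)
    }
    for (key in path_keys) {
      if (is.null(assign_to[[key]])) {
        assign_to[[key]] <- aid
        counts[aid] <- counts[aid] + 1L
      }
    }
  }
  # basin counts must be over initial free assignments, not over all states
  # on paths; recount by membership.
  counts <- integer(length(canons))
  for (r in seq_len(2L^f) - 1L) {
    key <- state_key(make_state(cn, int_to_bits(r, f)))
    aid <- assign_to[[key]]
    counts[aid] <- counts[aid] + 1L
  }
  attractors <- lapply(seq_along(canons), function(i) {
    new_attractor(canons[[i]], counts[i], 2L^f)
  })
  new_landscape(attractors, 2L^f, NULL, "exact", net$nodes)
}

#' Primary attractor of a landscape
#'
#' Returns the attractor with the largest basin; ties are broken by the
#' lexicographically smallest canonical state sequence, so the choice is
#' deterministic across runs and platforms.
#'
#' @param landscape A `bn_landscape`.
#' @return A `bn_attractor`.
#' @export
primary_attractor <- function(landscape) {
  stopifnot(inherits(landscape, "bn_landscape"))
  if (length(landscape$attractors) == 0L) {
    stop("empty landscape", call. = FALSE)
  }
  landscape$attractors[[landscape$primary_index]]
}

#' Sample initial states from one attractor's basin
#'
#' Rejection sampling: uniform random free-node states are drawn and kept
#' when their synchronous trajectory terminates in the target attractor
#' (canonical sequences equal), until `n` states are kept.  Duplicates are
#' allowed, as in any with-replacement sample.  If a probe of the first
#' `probe` draws accepts fewer than `floor * probe` states, sampling aborts
#' rather than loop indefinitely on a negligible basin.
#'
#' @inheritParams find_attractors
#' @param target A `bn_attractor` that occurs in the network's dynamics.
#' @param n Number of states to keep.
#' @param floor Minimal tolerated acceptance rate (default `1e-3`).
#' @param probe Number of draws in the acceptance-rate probe (default
#'   `1e4`).
#' @return A list of `n` full states.
#' @export
sample_basin_states <- function(net, target, n, seed = NULL,
                                max_steps = 10000L, floor = 1e-3,
                                probe = 10000L) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(target, "bn_attractor"), n >= 1L)
  cn <- compile_network(net)
  f <- length(cn$free_idx)
  reaches <- basin_membership_tester(cn, target$id, max_steps)
  with_seed(seed, {
    kept <- vector("list", n)
    n_kept <- 0L
    drawn <- 0L
    while (n_kept < n) {
      st <- make_state(cn, as.integer(runif(f) < 0.5))
      drawn <- drawn + 1L
      if (reaches(st)) {
        n_kept <- n_kept + 1L
        kept[[n_kept]] <- st
      }
      if (drawn == probe && n_kept < floor * probe) {
        stop("acceptance rate ", n_kept, "/", drawn,
             " below floor; basin too small to sample", call. = FALSE)
      }
    }
    kept
  })
}

# Memoized membership test: does a state's trajectory end in the attractor
# with canonical id `target_id`?  States along each queried trajectory are
# classified together, so repeated queries on overlapping basins are cheap.
basin_membership_tester <- function(cn, target_id, max_steps = 10000L) {
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  function(st) {
    path_keys <- character(0)
    path_pos <- new.env(parent = emptyenv(), hash = TRUE)
    verdict <- NA
    repeat {
      key <- state_key(st)
      known <- memo[[key]]
      if (!is.null(known)) { verdict <- known; break }
      p <- path_pos[[key]]
      if (!is.null(p)) {
        cyc_keys <- path_keys[p:length(path_keys)]
        canon <- canonical_cycle(lapply(cyc_keys, key_to_state))
        verdict <- identical(canon$id, target_id)
        break
      }
      path_keys <- c(path_keys, key)
      if (length(path_keys) > max_steps) {
        stop("horizon exceeded: no cycle within ", max_steps, " steps",
             call. = FALSE)
      }
      path_pos[[key]] <- length(path_keys)
      st <- compiled_step(cn, st)
    }
    for (key in path_keys) memo[[key]] <- verdict
    verdict
  }
}

#' Compare two attractor landscapes
#'
#' Matches attractors across two landscapes over the same node universe by
#' canonical form and compares their basin fractions; attractors present in
#' only one landscape are paired with fraction 0.
#'
#' @param a,b `bn_landscape` objects over the same node set.
#' @return A list with `shared` (number of attractors present in both),
#'   `pairs` (tibble of `attractor`, `fraction_a`, `fraction_b`) and
#'   `l1_distance` (the L1 distance between the basin-fraction vectors;
#'   ranges from 0 for identical landscapes to 2 for disjoint attractor
#'   sets).
#' @export
compare_landscapes <- function(a, b) {
  stopifnot(inherits(a, "bn_landscape"), inherits(b, "bn_landscape"))
  if (!identical(a$nodes, b$nodes)) {
    stop("landscapes are over different node universes", call. = FALSE)
  }
  fa <- setNames(vapply(a$attractors, function(x) x$basin_fraction,
                        numeric(1)),
                 vapply(a$attractors, function(x) x$id, character(1)))
  fb <- setNames(vapply(b$attractors, function(x) x$basin_fraction,
                        numeric(1)),
                 vapply(b$attractors, function(x) x$id, character(1)))
  ids <- union(names(fa), names(fb))
  pa <- ifelse(ids %in% names(fa), fa[ids], 0)
  pb <- ifelse(ids %in% names(fb), fb[ids], 0)
  list(
    shared = sum(ids %in% names(fa) & ids %in% names(fb)),
    pairs = tibble::tibble(attractor = ids, fraction_a = as.numeric(pa),
                           fraction_b = as.numeric(pb)),
    l1_distance = sum(abs(pa - pb))
  )
}
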