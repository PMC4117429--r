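# Edge-knockout decomposition of a Boolean network into an evolvable core
# and a robust neighbor, driven by preservation of the primary attractor.

#' Test whether an edge is insignificant
#'
#' An edge (u, v) is insignificant when the reduced tables of v obtained by
#' fixing u at 0 and at 1 are identical, i.e. the source's value never
#' changes the target's output.  Deleting such an edge leaves the
#' synchronous state-transition map bit-identical.
#'
#' @param net A [boolean_network()].
#' @param source,target Edge endpoints.
#' @return `TRUE` or `FALSE`.
#' @export
is_insignificant <- function(net, source, target) {
  tb <- net$tables[[target]]
  if (is.null(tb) || !source %in% tb$inputs) {
    stop("edge (", source, ", ", target, ") not in network", call. = FALSE)
  }
  identical(reduced_table(tb, source, 0L)$outputs,
            reduced_table(tb, source, 1L)$outputs)
}

#' Delete an edge from a Boolean network
#'
#' Removes the edge (u, v) by replacing the target's logic table with its
#' reduced table at `u = value`, eliminating u as a regulator of v.  The
#' node set is unchanged; deleting a node's last incoming edge leaves a
#' constant node.  The default `value = 0` matches the nominal condition in
#' which absent regulators are OFF.
#'
#' @inheritParams is_insignificant
#' @param value Value (0 or 1) at which the deleted input is fixed.
#' @return A new [boolean_network()].
#' @export
delete_edge <- function(net, source, target, value = 0L) {
  stopifnot(inherits(net, "boolean_network"))
  tb <- net$tables[[target]]
  if (is.null(tb) || !source %in% tb$inputs) {
    stop("edge (", source, ", ", target, ") not in network", call. = FALSE)
  }
  net$tables[[target]] <- reduced_table(tb, source, value)
  net
}

delete_edges <- function(net, edges, value = 0L) {
  for (i in seq_len(nrow(edges))) {
    net <- delete_edge(net, edges$source[i], edges$target[i], value)
  }
  net
}

#' Test whether a candidate network preserves the primary attractor
#'
#' Runs every supplied basin state to its attractor in the candidate
#' network and checks that the terminal cycle's canonical form equals the
#' primary attractor's.  By default every state must be retained
#' (`min_fraction = 1`); a trajectory whose horizon is exceeded counts as
#' not preserved.
#'
#' @param net_candidate The perturbed [boolean_network()].
#' @param basin_states List of states sampled from the original primary
#'   basin.
#' @param primary The original primary attractor (`bn_attractor`).
#' @param min_fraction Minimal fraction of states that must still reach the
#'   primary attractor.
#' @param max_steps Trajectory horizon.
#' @return `TRUE` or `FALSE`.
#' @export
preserves_primary <- function(net_candidate, basin_states, primary,
                              min_fraction = 1, max_steps = 10000L) {
  stopifnot(inherits(net_candidate, "boolean_network"),
            inherits(primary, "bn_attractor"))
  cn <- compile_network(net_candidate)
  preserves_primary_compiled(cn, basin_states, primary$id, min_fraction,
                             max_steps)
}

preserves_primary_compiled <- function(cn, basin_states, primary_id,
                                       min_fraction = 1,
                                       max_steps = 10000L) {
  reaches <- basin_membership_tester(cn, primary_id, max_steps)
  n <- length(basin_states)
  ok <- 0L
  budget <- (1 - min_fraction) * n
  failed <- 0L
  for (st in basin_states) {
    hit <- tryCatch(reaches(st), error = function(e) FALSE)
    if (hit) ok <- ok + 1L else {
      failed <- failed + 1L
      if (failed > budget) return(FALSE)
    }
  }
  ok >= min_fraction * n
}

#' Decompose a Boolean network into evolvable core and robust neighbor
#'
#' Implements the edge-knockout decomposition: (a) estimate the attractor
#' landscape from `n_samples` random initial states and identify the
#' primary attractor; (b) sample `n_samples` initial states from its basin
#' (fixed once and reused for every subsequent test); (c) remove all
#' insignificant edges; (d) screen the remaining edges for candidates whose
#' single deletion preserves the primary attractor; (e) repeatedly draw a
#' uniformly random candidate, re-test it on the current reduced network,
#' delete it if the primary attractor is preserved and discard it
#' otherwise; (f) when the candidate set is exhausted, rebuild it on the
#' current network, and stop when no edge is singly deletable.  The edges
#' remaining at the end form the evolvable core; all deleted edges form the
#' robust neighbor.
#'
#' Randomness flows from two named seeds: `seed_init` drives the
#' initial-state and basin sampling, `seed_order` the random deletion
#' order.
#'
#' @param net A [boolean_network()].
#' @param n_samples Number of initial states for both the landscape and the
#'   basin sample.
#' @param seed_init,seed_order Integer seeds.
#' @param delete_value Value at which deleted inputs are fixed (default 0,
#'   the nominal OFF condition).
#' @param min_fraction Preservation threshold passed to
#'   [preserves_primary()] (default 1: every sampled state must be
#'   retained).
#' @param max_steps Trajectory horizon.
#' @return An object of class `bn_decomposition` with elements
#'   `core_edges`, `neighbor_edges` (tibbles), `provenance` (per-edge class
#'   and reason: `insignificant`, `candidate_deleted` or `retained`),
#'   `deletion_order`, `seeds`, `sample_size`, `landscape`, `primary` and
#'   the deduplicated `basin_states` used for testing.
#' @examples
#' dec <- decompose(fixture_network("TOY3"), n_samples = 50,
#'                  seed_init = 1, seed_order = 2)
#' tidy(dec)
#' @export
decompose <- function(net, n_samples = 10000L, seed_init = 1L,
                      seed_order = 2L, delete_value = 0L,
                      min_fraction = 1, max_steps = 10000L) {
  stopifnot(inherits(net, "boolean_network"))
  landscape <- find_attractors(net, n_samples, seed = seed_init,
                               max_steps = max_steps)
  primary <- primary_attractor(landscape)
  basin_raw <- sample_basin_states(net, primary, n_samples,
                                   seed = seed_init + 1L,
                                   max_steps = max_steps)
  # preservation must hold for every sampled state, so duplicates are
  # redundant work; keep the distinct states
  basin <- basin_raw[!duplicated(vapply(basin_raw, state_key, character(1)))]

  cur <- net
  prov <- list()
  order_log <- list()
  note_deletion <- function(source, target, phase) {
    order_log[[length(order_log) + 1L]] <<-
      tibble::tibble(source = source, target = target, phase = phase)
    prov[[edge_id(source, target)]] <<- phase
  }

  # (c) single sweep removing insignificant edges, lexicographic order,
  # re-checked against the current (already reduced) tables
  for_edges <- network_edges(cur)
  for (i in seq_len(nrow(for_edges))) {
    s <- for_edges$source[i]; t <- for_edges$target[i]
    if (is_insignificant(cur, s, t)) {
      cur <- delete_edge(cur, s, t, delete_value)
      note_deletion(s, t, "insignificant")
    }
  }

  screen <- function(cur) {
    eds <- network_edges(cur)
    keep <- vapply(seq_len(nrow(eds)), function(i) {
      cand <- delete_edge(cur, eds$source[i], eds$target[i], delete_value)
      preserves_primary_compiled(compile_network(cand), basin, primary$id,
                                 min_fraction, max_steps)
    }, logical(1))
    eds[keep, , drop = FALSE]
  }

  # (d)-(f) randomized deletion driven by seed_order
  with_seed(seed_order, {
    repeat {
      er <- screen(cur)
      if (nrow(er) == 0L) break
      deleted_any <- FALSE
      while (nrow(er) > 0L) {
        i <- if (nrow(er) == 1L) 1L else sample.int(nrow(er), 1L)
        s <- er$source[i]; t <- er$target[i]
        er <- er[-i, , drop = FALSE]
        cand <- delete_edge(cur, s, t, delete_value)
        if (preserves_primary_compiled(compile_network(cand), basin,
                                       primary$id, min_fraction,
                                       max_steps)) {
          cur <- cand
          deleted_any <- TRUE
          note_deletion(s, t, "candidate_deleted")
        }
      }
      if (!deleted_any) break
    }
  })

  core <- network_edges(cur)
  all_edges <- network_edges(net)
  ids <- edge_id(all_edges$source, all_edges$target)
  core_ids <- edge_id(core$source, core$target)
  provenance <- tibble::tibble(
    source = all_edges$source, target = all_edges$target,
    class = ifelse(ids %in% core_ids, "core", "neighbor"),
    provenance = vapply(ids, function(id) prov[[id]] %||% "retained",
                        character(1), USE.NAMES = FALSE)
  )
  structure(
    list(core_edges = core,
         neighbor_edges = sort_edges(
           all_edges[!ids %in% core_ids, , drop = FALSE]),
         provenance = provenance,
         deletion_order = if (length(order_log)) {
           dplyr::mutate(dplyr::bind_rows(order_log),
                         step = dplyr::row_number(), .before = 1)
         } else {
           tibble::tibble(step = integer(), source = character(),
                          target = character(), phase = character())
         },
         seeds = list(initial_state_seed = seed_init,
                      deletion_seed = seed_order),
         sample_size = n_samples,
         delete_value = delete_value,
         landscape = landscape,
         primary = primary,
         basin_states = basin),
    class = "bn_decomposition"
  )
}

#' @export
print.bn_decomposition <- function(x, ...) {
  cat("<bn_decomposition> core ", nrow(x$core_edges), " edge(s), neighbor ",
      nrow(x$neighbor_edges), " edge(s)\n", sep = "")
  cat("  neighbor provenance: ",
      paste(names(table(x$provenance$provenance[
        x$provenance$class == "neighbor"])),
        table(x$provenance$provenance[x$provenance$class == "neighbor"]),
        sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-node evolvability and robustness scores
#'
#' A node's evolvability score is the fraction of its incident edges
#' (incoming and outgoing) that belong to the evolvable core; the
#' robustness score is the complementary fraction in the robust neighbor.
#' Nodes with no incident edge carry no score and are omitted.
#'
#' @param net The decomposed [boolean_network()].
#' @param decomposition A [decompose()] result for `net`.
#' @return A tibble with columns `node`, `degree`, `n_core`, `n_neighbor`,
#'   `evolvability` and `robustness`.
#' @export
node_scores <- function(net, decomposition) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(decomposition, "bn_decomposition"))
  prov <- decomposition$provenance
  incid <- dplyr::bind_rows(
    dplyr::select(prov, node = "source", "class"),
    dplyr::select(prov, node = "target", "class")
  )
  out <- dplyr::summarise(
    dplyr::group_by(incid, .data$node),
    degree = dplyr::n(),
    n_core = sum(.data$class == "core"),
    n_neighbor = sum(.data$class == "neighbor"),
    .groups = "drop"
  )
  out <- dplyr::mutate(out,
                       evolvability = .data$n_core / .data$degree,
                       robustness = .data$n_neighbor / .data$degree)
  dplyr::arrange(out, .data$node)
}

#' Verify the definitional contracts of a decomposition
#'
#' Checks that (a) the core sub-network alone still sends every sampled
#' basin state to the original primary attractor, (b) the core is minimal:
#' deleting any single core edge from the core network breaks preservation,
#' and (c) core and neighbor partition the original edge set.
#'
#' @inheritParams node_scores
#' @param basin_states Optional list of basin states (defaults to the ones
#'   stored in the decomposition).
#' @param max_steps Trajectory horizon.
#' @return A tibble with columns `check`, `pass` and `detail`.
#' @export
verify_decomposition <- function(net, decomposition, basin_states = NULL,
                                 max_steps = 10000L) {
  stopifnot(inherits(decomposition, "bn_decomposition"))
  basin <- basin_states %||% decomposition$basin_states
  primary <- decomposition$primary
  value <- decomposition$delete_value
  core_net <- delete_edges(net, decomposition$neighbor_edges, value)

  partition_ok <- {
    all_edges <- network_edges(net)
    ids <- sort(edge_id(all_edges$source, all_edges$target))
    got <- sort(c(edge_id(decomposition$core_edges$source,
                          decomposition$core_edges$target),
                  edge_id(decomposition$neighbor_edges$source,
                          decomposition$neighbor_edges$target)))
    identical(ids, got) &&
      nrow(decomposition$core_edges) + nrow(decomposition$neighbor_edges) ==
        nrow(all_edges)
  }
  preserved <- preserves_primary(core_net, basin, primary,
                                 max_steps = max_steps)
  core <- decomposition$core_edges
  deletable <- character(0)
  for (i in seq_len(nrow(core))) {
    cand <- delete_edge(core_net, core$source[i], core$target[i], value)
    if (preserves_primary(cand, basin, primary, max_steps = max_steps)) {
      deletable <- c(deletable,
                     paste0("(", core$source[i], ",", core$target[i], ")"))
    }
  }
  tibble::tibble(
    check = c("core_preserves_primary", "core_minimal", "edge_partition"),
    pass = c(preserved, length(deletable) == 0L, partition_ok),
    detail = c(
      if (preserved) "all basin states reach the primary attractor"
      else "some basin state escapes the primary attractor",
      if (length(deletable) == 0L) "no single core edge is deletable"
      else paste("deletable core edge(s):",
                 paste(deletable, collapse = " ")),
      if (partition_ok) "core and neighbor partition the edge set"
      else "core/neighbor do not partition the edge set"
    )
  )
}

#' Chi-square overlap test between two decompositions
#'
#' Cross-tabulates core/neighbor membership of every edge under two
#' decompositions of the same edge universe and tests the association with
#' a 2x2 chi-square test (without continuity correction).  The one-sided
#' p-value is halved in the direction of positive agreement (and reflected
#' when the observed association is negative).  The raw Jaccard index of
#' the two core sets is reported alongside.
#'
#' @param d1,d2 [decompose()] results over the same edge universe.
#' @return A list with `table` (2x2 contingency matrix), `statistic`,
#'   `p_value` (one-sided) and `jaccard_core`.
#' @export
decomposition_overlap_test <- function(d1, d2) {
  stopifnot(inherits(d1, "bn_decomposition"),
            inherits(d2, "bn_decomposition"))
  id1 <- edge_id(d1$provenance$source, d1$provenance$target)
  id2 <- edge_id(d2$provenance$source, d2$provenance$target)
  if (!setequal(id1, id2)) {
    stop("decompositions cover different edge universes", call. = FALSE)
  }
  c1 <- setNames(d1$provenance$class, id1)
  c2 <- setNames(d2$provenance$class, id2)[id1]
  tab <- table(factor(c1, c("core", "neighbor")),
               factor(c2, c("core", "neighbor")))
  res <- overlap_chisq(unclass(tab))
  core1 <- id1[c1 == "core"]
  core2 <- names(c2)[c2 == "core"]
  res$jaccard_core <- length(intersect(core1, core2)) /
    length(union(core1, core2))
  res$table <- tab
  res
}

# One-sided chi-square on a 2x2 table: halved two-sided p when the observed
# association is in the positive (agreement) direction.
overlap_chisq <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == 2L))
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  stat <- sum((m - expected)^2 / expected)
  p2 <- pchisq(stat, df = 1, lower.tail = FALSE)
  positive <- m[1, 1] >= expected[1, 1]
  p1 <- if (positive) p2 / 2 else 1 - p2 / 2
  list(statistic = stat, p_value = min(max(p1, .Machine$double.xmin), 1))
}

#' New attractors created by single core-edge deletions
#'
#' Deletes each evolvable-core edge in turn from the network, runs every
#' sampled basin state in the perturbed network, and collects the distinct
#' attractors other than the original primary.  Each collected attractor is
#' compared against the original landscape's full attractor list, and the
#' fraction absent from it (genuinely new attractors) is reported.
#'
#' @inheritParams verify_decomposition
#' @param landscape Optional original landscape (defaults to the one stored
#'   in the decomposition).
#' @return A list with `per_edge` (tibble: edge, number of distinct
#'   non-primary attractors reached, number of those absent from the
#'   original attractor list), `total_new_attractors` (summed over edges)
#'   and `fraction_not_in_original`.
#' @export
perturbation_novelty <- function(net, decomposition, basin_states = NULL,
                                 landscape = NULL, max_steps = 10000L) {
  stopifnot(inherits(decomposition, "bn_decomposition"))
  basin <- basin_states %||% decomposition$basin_states
  land <- landscape %||% decomposition$landscape
  primary_id <- decomposition$primary$id
  known_ids <- vapply(land$attractors, function(a) a$id, character(1))
  core <- decomposition$core_edges
  value <- decomposition$delete_value
  rows <- lapply(seq_len(nrow(core)), function(i) {
    cand <- delete_edge(net, core$source[i], core$target[i], value)
    cn <- compile_network(cand)
    got <- new.env(parent = emptyenv(), hash = TRUE)
    for (st in basin) {
      tr <- tryCatch(compiled_run_to_cycle(cn, st, max_steps),
                     error = function(e) NULL)
      if (is.null(tr)) next # horizon exceeded for this state; logged as skipped
      canon <- canonical_cycle(tr$cycle)
      if (canon$id != primary_id) got[[canon$id]] <- TRUE
    }
    ids <- ls(got)
    tibble::tibble(source = core$source[i], target = core$target[i],
                   n_attractors = length(ids),
                   n_new = sum(!ids %in% known_ids),
                   attractors = list(ids))
  })
  per_edge <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(source = character(), target = character(),
                   n_attractors = integer(), n_new = integer(),
                   attractors = list())
  total <- sum(per_edge$n_attractors)
  list(per_edge = per_edge,
       total_new_attractors = total,
       fraction_not_in_original = if (total > 0) sum(per_edge$n_new) / total
                                  else NA_real_)
}
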