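# Structural statistics of (sub-)networks and the random-deletion /
# random-selection null ensembles.

#' Sub-network container
#'
#' A lightweight directed sub-network: an edge table plus the retained node
#' set.  Topology statistics accept a [boolean_network()], a `bn_subnetwork`
#' or a plain tibble with `source`/`target` columns.
#'
#' @param edges Tibble with `source` and `target` columns.
#' @param nodes Character vector of retained nodes (defaults to the edge
#'   endpoints).
#' @return An object of class `bn_subnetwork`.
#' @export
subnetwork <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  edges <- sort_edges(edge_tbl(edges$source, edges$target))
  nodes <- nodes %||% unique(c(edges$source, edges$target))
  structure(list(edges = edges, nodes = as.character(nodes)),
            class = "bn_subnetwork")
}

#' @export
print.bn_subnetwork <- function(x, ...) {
  cat("<bn_subnetwork> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

# Normalize any accepted graph argument to list(edges, nodes).
as_graph_parts <- function(x) {
  if (inherits(x, "boolean_network")) {
    list(edges = network_edges(x), nodes = x$nodes)
  } else if (inherits(x, "bn_subnetwork")) {
    list(edges = x$edges, nodes = x$nodes)
  } else if (is.data.frame(x)) {
    g <- subnetwork(x)
    list(edges = g$edges, nodes = g$nodes)
  } else {
    stop("expected a boolean_network, bn_subnetwork or edge table",
         call. = FALSE)
  }
}

graph_adjacency <- function(parts) {
  n <- length(parts$nodes)
  A <- matrix(0L, n, n, dimnames = list(parts$nodes, parts$nodes))
  if (nrow(parts$edges)) {
    A[cbind(match(parts$edges$source, parts$nodes),
            match(parts$edges$target, parts$nodes))] <- 1L
  }
  A
}

#' Count short feedback loops
#'
#' Counts the distinct simple directed cycles of exactly `k` nodes for
#' `k` in 1 (self-loops), 2 (two-node feedbacks) and 3 (three-node
#' feedbacks).  A two-node feedback u<->v counts once; a three-node set
#' carrying both cycle orientations counts twice (once per directed
#' traversal).  Logic and interaction sign are ignored.
#'
#' @param net A network, sub-network or edge table.
#' @param k Cycle length, one of 1, 2, 3.
#' @return Integer count.
#' @examples
#' count_feedbacks(fixture_network("TRIAD"), 3)
#' @export
count_feedbacks <- function(net, k) {
  stopifnot(length(k) == 1L, k %in% c(1L, 2L, 3L))
  A <- graph_adjacency(as_graph_parts(net))
  A0 <- A
  diag(A0) <- 0L
  switch(as.character(k),
    "1" = sum(diag(A)),
    "2" = sum(A0 * t(A0)) / 2,
    "3" = sum(diag(A0 %*% A0 %*% A0)) / 3
  )
}

#' Feedback-loop census
#'
#' @inheritParams count_feedbacks
#' @return A tibble with `self_loops`, `two_node_feedbacks` and
#'   `three_node_feedbacks`.
#' @export
feedback_census <- function(net) {
  tibble::tibble(
    self_loops = count_feedbacks(net, 1L),
    two_node_feedbacks = count_feedbacks(net, 2L),
    three_node_feedbacks = count_feedbacks(net, 3L)
  )
}

#' Degree heterogeneity
#'
#' Variance of the total-degree (in + out) distribution divided by its
#' mean, a scalar proxy for scale-freeness: 0 for regular graphs, large for
#' hub-dominated ones.  The population (not sample) variance is used, and
#' the degree distribution runs over the retained node set.
#'
#' @inheritParams count_feedbacks
#' @return A non-negative ratio.
#' @export
degree_heterogeneity <- function(net) {
  parts <- as_graph_parts(net)
  deg <- node_degrees(parts)
  if (all(deg == 0)) stop("all nodes are isolated", call. = FALSE)
  m <- mean(deg)
  v <- mean((deg - m)^2)
  v / m
}

node_degrees <- function(parts) {
  deg <- setNames(numeric(length(parts$nodes)), parts$nodes)
  if (nrow(parts$edges)) {
    tb <- table(c(parts$edges$source, parts$edges$target))
    deg[names(tb)] <- as.numeric(tb)
  }
  deg
}

#' Degree histogram
#'
#' @inheritParams count_feedbacks
#' @return A tibble with columns `degree` and `n_nodes`.
#' @export
degree_histogram <- function(net) {
  deg <- node_degrees(as_graph_parts(net))
  tb <- table(deg)
  tibble::tibble(degree = as.integer(names(tb)), n_nodes = as.integer(tb))
}

#' Characteristic path length
#'
#' Mean directed shortest-path length over all ordered node pairs (u, v),
#' u != v, with a finite distance; unreachable pairs are excluded from the
#' mean rather than imputed.
#'
#' @inheritParams count_feedbacks
#' @return Mean length (>= 1 whenever any reachable pair exists).
#' @export
characteristic_path_length <- function(net) {
  parts <- as_graph_parts(net)
  g <- igraph::graph_from_data_frame(parts$edges, directed = TRUE,
                                     vertices = parts$nodes)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  if (length(finite) == 0L) stop("no reachable ordered pair", call. = FALSE)
  mean(finite)
}

#' Number of connected components
#'
#' Weakly connected components of the sub-network induced by its edges and
#' their endpoints; nodes without any incident edge are excluded from the
#' count (a retained but edge-free node is not a component).
#'
#' @inheritParams count_feedbacks
#' @return Integer count (0 for an edge-free graph).
#' @export
connected_components <- function(net) {
  parts <- as_graph_parts(net)
  if (nrow(parts$edges) == 0L) return(0L)
  touched <- unique(c(parts$edges$source, parts$edges$target))
  g <- igraph::graph_from_data_frame(parts$edges, directed = TRUE,
                                     vertices = touched)
  igraph::count_components(g, mode = "weak")
}

#' All structural statistics of a network
#'
#' @inheritParams count_feedbacks
#' @return A one-row tibble with the feedback census, degree heterogeneity,
#'   characteristic path length and component count (`NA` where a statistic
#'   is undefined on the graph).
#' @export
topology_stats <- function(net) {
  safe <- function(f) tryCatch(f(net), error = function(e) NA_real_)
  dplyr::bind_cols(
    feedback_census(net),
    tibble::tibble(
      degree_heterogeneity = safe(degree_heterogeneity),
      characteristic_path_length = safe(characteristic_path_length),
      n_components = as.numeric(connected_components(net))
    )
  )
}

#' Random sub-network null models
#'
#' `random_deletion_subnetwork()` deletes `m` uniformly random edges (the
#' null model for an evolvable core of size `|E| - m`);
#' `random_selection_subnetwork()` keeps `m` uniformly random edges (the
#' null model for a robust neighbor of size `m`).  Both sample without
#' replacement, retain the full node set and are seeded.
#'
#' @inheritParams count_feedbacks
#' @param m Number of edges to delete (resp. select); `0 <= m <= |E|`.
#' @param seed Optional integer seed.
#' @return A [subnetwork()].
#' @export
random_deletion_subnetwork <- function(net, m, seed = NULL) {
  parts <- as_graph_parts(net)
  ne <- nrow(parts$edges)
  stopifnot(m >= 0L, m <= ne)
  with_seed(seed, {
    drop <- if (m > 0L) sample.int(ne, m) else integer(0)
    keep <- setdiff(seq_len(ne), drop)
    subnetwork(parts$edges[keep, , drop = FALSE], parts$nodes)
  })
}

#' @rdname random_deletion_subnetwork
#' @export
random_selection_subnetwork <- function(net, m, seed = NULL) {
  parts <- as_graph_parts(net)
  ne <- nrow(parts$edges)
  stopifnot(m >= 0L, m <= ne)
  with_seed(seed, {
    keep <- if (m > 0L) sample.int(ne, m) else integer(0)
    subnetwork(parts$edges[sort(keep), , drop = FALSE], parts$nodes)
  })
}

#' Compare an observed sub-network statistic against a null ensemble
#'
#' Builds `replicates` random sub-networks from the full network (random
#' edge deletion or random edge selection of the same size as the observed
#' sub-network), computes the chosen statistic on each, and tests whether
#' the observed value lies above (`direction = "greater"`) or below
#' (`direction = "less"`) the null distribution with a one-sided t test.
#' With a single observed sub-network this is the one-sample t test of the
#' null values against the observed value; when `observed_value` carries
#' several replicate measurements (e.g. cores from several seeds) the
#' one-sided Welch two-sample t test is used.
#'
#' @param observed_subnet The observed sub-network (network, sub-network or
#'   edge table).
#' @param net The full network the nulls are drawn from.
#' @param m Number of edges deleted (resp. selected) in each null
#'   replicate; defaults to matching the observed sub-network's size.
#' @param statistic One of `"self_loops"`, `"two_node_feedbacks"`,
#'   `"three_node_feedbacks"`, `"degree_heterogeneity"`,
#'   `"characteristic_path_length"`, `"n_components"`.
#' @param replicates Number of null sub-networks (default 100).
#' @param direction `"greater"` or `"less"` (observed vs null).
#' @param null Null model: `"deletion"` or `"selection"`.
#' @param seed Optional integer seed.
#' @param observed_value Optional precomputed observed statistic value(s),
#'   overriding computation from `observed_subnet`.
#' @return An object of class `bn_null_ensemble` with `observed`,
#'   `null_values`, `statistic`, `direction`, `p_value` and
#'   `degenerate_null` (flag set when the null variance hit the numerical
#'   floor).
#' @export
null_comparison <- function(observed_subnet, net, m = NULL,
                            statistic = "three_node_feedbacks",
                            replicates = 100L,
                            direction = c("greater", "less"),
                            null = c("deletion", "selection"),
                            seed = NULL, observed_value = NULL) {
  direction <- match.arg(direction)
  null <- match.arg(null)
  stopifnot(replicates >= 2L)
  stat_fun <- topology_statistic(statistic)
  obs_parts <- as_graph_parts(observed_subnet)
  full_parts <- as_graph_parts(net)
  if (is.null(m)) {
    m <- if (null == "deletion") {
      nrow(full_parts$edges) - nrow(obs_parts$edges)
    } else {
      nrow(obs_parts$edges)
    }
  }
  observed <- observed_value %||% stat_fun(observed_subnet)
  nulls <- with_seed(seed, vapply(seq_len(replicates), function(i) {
    sub <- if (null == "deletion") {
      random_deletion_subnetwork(net, m)
    } else {
      random_selection_subnetwork(net, m)
    }
    stat_fun(sub)
  }, numeric(1)))
  res <- one_sided_t(observed, nulls, direction)
  structure(
    list(observed = observed, null_values = nulls, statistic = statistic,
         m = m, null = null, direction = direction,
         p_value = res$p, degenerate_null = res$degenerate),
    class = "bn_null_ensemble"
  )
}

topology_statistic <- function(statistic) {
  switch(statistic,
    self_loops = function(x) count_feedbacks(x, 1L),
    two_node_feedbacks = function(x) count_feedbacks(x, 2L),
    three_node_feedbacks = function(x) count_feedbacks(x, 3L),
    degree_heterogeneity = degree_heterogeneity,
    characteristic_path_length = characteristic_path_length,
    n_components = function(x) as.numeric(connected_components(x)),
    stop("unknown statistic '", statistic, "'", call. = FALSE)
  )
}

# One-sided t test of an observed value (or replicate vector) against the
# null sample.  direction = "greater" asks whether the observed exceeds the
# null distribution.
one_sided_t <- function(observed, nulls, direction) {
  degenerate <- FALSE
  if (length(observed) >= 2L) {
    alt <- if (direction == "greater") "greater" else "less"
    if (sd(observed) == 0 && sd(nulls) == 0) {
      degenerate <- TRUE
      p <- if (mean(observed) == mean(nulls)) 0.5
           else if (xor(mean(observed) > mean(nulls),
                        direction == "less")) .Machine$double.xmin else 1
    } else {
      p <- stats::t.test(observed, nulls, alternative = alt,
                         var.equal = FALSE)$p.value
    }
  } else {
    n <- length(nulls)
    s <- sd(nulls)
    if (s == 0) {
      degenerate <- TRUE
      s <- .Machine$double.eps^0.5
    }
    tstat <- (mean(nulls) - observed) / (s / sqrt(n))
    # observed greater than nulls <=> tstat very negative
    p <- if (direction == "greater") pt(tstat, df = n - 1)
         else pt(tstat, df = n - 1, lower.tail = FALSE)
  }
  list(p = min(max(p, .Machine$double.xmin), 1), degenerate = degenerate)
}

#' @export
print.bn_null_ensemble <- function(x, ...) {
  cat("<bn_null_ensemble> ", x$statistic, ": observed ",
      format(x$observed, digits = 4), " vs ", length(x$null_values),
      " nulls (mean ", format(mean(x$null_values), digits = 4),
      "), one-sided p = ", format(x$p_value, digits = 3),
      if (x$degenerate_null) " [degenerate null variance]", "\n", sep = "")
  invisible(x)
}

#' Robust-neighbor link ratio per degree bin
#'
#' For each node-degree bin, the fraction of edge incidences at nodes in
#' the bin that belong to the robust neighbor; an edge contributes once per
#' incident binned node.  Node degrees are total degrees in the full
#' network.  Default bins follow the low/middle/high split 2--5, 6--9 and
#' 10--42.
#'
#' @inheritParams node_scores
#' @param bins Named list of integer degree ranges.
#' @return A tibble with `bin`, `n_incidences`, `n_neighbor` and `ratio`
#'   (`NA` for empty bins).
#' @export
degree_bin_neighbor_ratio <- function(net, decomposition,
                                      bins = list(low = 2:5, middle = 6:9,
                                                  high = 10:42)) {
  stopifnot(inherits(decomposition, "bn_decomposition"))
  deg <- node_degrees(as_graph_parts(net))
  prov <- decomposition$provenance
  rows <- lapply(names(bins), function(bn) {
    members <- names(deg)[deg %in% bins[[bn]]]
    inc_src <- prov$source %in% members
    inc_tgt <- prov$target %in% members
    n_inc <- sum(inc_src) + sum(inc_tgt)
    n_nb <- sum(inc_src & prov$class == "neighbor") +
      sum(inc_tgt & prov$class == "neighbor")
    tibble::tibble(bin = bn, n_incidences = n_inc, n_neighbor = n_nb,
                   ratio = if (n_inc > 0L) n_nb / n_inc else NA_real_)
  })
  dplyr::bind_rows(rows)
}
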