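#' Boolean network
#'
#' A Boolean network is a directed graph together with one logic table per
#' regulated node.  Nodes with no table and no incoming edge are input nodes
#' (ligands and other external signals); their state is clamped to a fixed
#' value at every step, 0 ("OFF") by default, so the nominal dynamics of the
#' system are simulated without external stimulation.  Nodes with an empty
#' input list but a one-row table are constants, not inputs.
#'
#' @param tables List of [logic_table()] objects, one per regulated node.
#' @param inputs Character vector of input-node ids.  Nodes referenced as
#'   regulators but carrying no table are added automatically.
#' @param clamp Named 0/1 vector of clamp values for input nodes; unnamed
#'   inputs default to 0.
#' @param nodes Optional explicit node ordering; defaults to inputs followed
#'   by table targets, in the order given.
#' @return An object of class `boolean_network`.
#' @examples
#' toy <- boolean_network(
#'   tables = list(
#'     logic_table("B", c("A", "C"), c(0, 1, 1, 1)),
#'     logic_table("C", "B", c(0, 1))
#'   ),
#'   inputs = "A"
#' )
#' toy
#' @export
boolean_network <- function(tables, inputs = character(), clamp = NULL,
                            nodes = NULL) {
  stopifnot(is.list(tables))
  tables <- lapply(tables, function(tb) {
    stopifnot(inherits(tb, "logic_table"))
    tb
  })
  targets <- vapply(tables, function(tb) tb$target, character(1))
  if (anyDuplicated(targets)) {
    stop("duplicate table for node '", targets[duplicated(targets)][1L], "'",
         call. = FALSE)
  }
  names(tables) <- targets
  referenced <- unique(unlist(lapply(tables, function(tb) tb$inputs)))
  inputs <- union(as.character(inputs), setdiff(referenced, targets))
  if (length(bad <- intersect(inputs, targets))) {
    stop("node '", bad[1L], "' declared as input but carries a table",
         call. = FALSE)
  }
  all_nodes <- nodes %||% c(inputs, targets)
  if (!setequal(all_nodes, c(inputs, targets)) || anyDuplicated(all_nodes)) {
    stop("'nodes' must be a permutation of the input and table nodes",
         call. = FALSE)
  }
  cl <- setNames(rep(0L, length(inputs)), inputs)
  if (!is.null(clamp)) {
    stopifnot(!is.null(names(clamp)), all(names(clamp) %in% inputs),
              all(clamp %in% c(0, 1)))
    cl[names(clamp)] <- as.integer(clamp)
  }
  net <- structure(
    list(nodes = as.character(all_nodes), tables = tables,
         inputs = inputs, clamp = cl),
    class = "boolean_network"
  )
  issues <- validate_network(net)
  if (nrow(issues)) {
    stop("invalid network: ", issues$message[1L], call. = FALSE)
  }
  net
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("<boolean_network> ", n_nodes(x), " nodes, ", n_edges(x), " edges, ",
      length(x$inputs), " input node(s)\n", sep = "")
  if (length(x$inputs)) {
    cat("  inputs clamped: ",
        paste0(x$inputs, "=", x$clamp[x$inputs], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Network accessors
#'
#' `n_nodes()` and `n_edges()` count nodes and directed edges;
#' `network_edges()` returns the edge list as a tibble (derived from the
#' logic-table inputs, sorted lexicographically); `input_nodes()` returns
#' the clamped input nodes; `free_nodes()` the nodes whose state is not
#' clamped.
#'
#' @param net A [boolean_network()].
#' @return Counts, a `tibble` with `source`/`target` columns, or character
#'   vectors of node ids.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(network_edges(net))

#' @rdname n_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  src <- unlist(lapply(net$tables, function(tb) tb$inputs), use.names = FALSE)
  tgt <- rep(names(net$tables),
             vapply(net$tables, function(tb) length(tb$inputs), integer(1)))
  sort_edges(edge_tbl(src, tgt))
}

#' @rdname n_nodes
#' @export
input_nodes <- function(net) net$inputs

#' @rdname n_nodes
#' @export
free_nodes <- function(net) setdiff(net$nodes, net$inputs)

#' Override input-node clamp values
#'
#' Input nodes are held at their clamp value at every update step.  The
#' default clamp is 0 for every input; individual ligands can be switched ON
#' to reproduce stimulated conditions.
#'
#' @param net A [boolean_network()].
#' @param ... Named 0/1 values, e.g. `set_clamp(net, EGF = 1)`, or a single
#'   named vector.
#' @return The modified network.
#' @export
set_clamp <- function(net, ...) {
  stopifnot(inherits(net, "boolean_network"))
  vals <- c(...)
  stopifnot(!is.null(names(vals)), all(vals %in% c(0, 1)))
  if (length(bad <- setdiff(names(vals), net$inputs))) {
    stop("'", bad[1L], "' is not an input node", call. = FALSE)
  }
  net$clamp[names(vals)] <- as.integer(vals)
  net
}

#' Check the structural invariants of a Boolean network
#'
#' Reports, rather than raises, violations of the data-model contract:
#' table lengths must be `2^k`, outputs binary, every table input must have a
#' matching edge endpoint declared as a node, input nodes must have in-degree
#' zero, and no node may carry two tables.  An empty report means the network
#' is valid.
#'
#' @param net A `boolean_network` (or a structurally similar list, so that
#'   broken objects can be inspected).
#' @return A tibble with columns `kind`, `node` and `message`, one row per
#'   violation; zero rows when all invariants hold.
#' @export
validate_network <- function(net) {
  issues <- list()
  note <- function(kind, node, message) {
    issues[[length(issues) + 1L]] <<-
      tibble::tibble(kind = kind, node = node, message = message)
  }
  known <- net$nodes
  for (tb in net$tables) {
    if (length(tb$outputs) != 2L^length(tb$inputs)) {
      note("table_length", tb$target,
           paste0("table for '", tb$target, "' has ", length(tb$outputs),
                  " rows; expected 2^", length(tb$inputs)))
    }
    if (!all(tb$outputs %in% c(0L, 1L))) {
      note("non_binary_output", tb$target,
           paste0("table for '", tb$target, "' has a non-binary output"))
    }
    if (anyDuplicated(tb$inputs)) {
      note("duplicate_input", tb$target,
           paste0("table for '", tb$target, "' lists a duplicate input"))
    }
    for (u in setdiff(tb$inputs, known)) {
      note("undeclared_node", u,
           paste0("table for '", tb$target, "' references undeclared node '",
                  u, "'"))
    }
  }
  for (v in net$inputs) {
    if (v %in% names(net$tables)) {
      note("input_with_table", v,
           paste0("input node '", v, "' carries a table"))
    }
  }
  incoming <- unique(unlist(lapply(net$tables, function(tb) tb$target)))
  for (v in intersect(net$inputs, incoming)) {
    note("edge_table_mismatch", v,
         paste0("input node '", v, "' has an incoming edge"))
  }
  if (length(issues) == 0L) {
    return(tibble::tibble(kind = character(), node = character(),
                          message = character()))
  }
  dplyr::bind_rows(issues)
}

# --- internal compiled form for fast simulation -----------------------------

# Precomputes per-table node indices and row weights so that a synchronous
# step is a handful of vector operations.
compile_network <- function(net) {
  nodes <- net$nodes
  clamp_idx <- match(net$inputs, nodes)
  tabs <- lapply(net$tables, function(tb) {
    k <- length(tb$inputs)
    list(j = match(tb$target, nodes),
         idx = match(tb$inputs, nodes),
         w = bit_weights(k),
         out = tb$outputs)
  })
  list(n = length(nodes), nodes = nodes, tabs = tabs,
       clamp_idx = clamp_idx, clamp_val = unname(net$clamp),
       free_idx = setdiff(seq_along(nodes), clamp_idx))
}

compiled_step <- function(cn, state) {
  nxt <- state
  for (tb in cn$tabs) {
    nxt[tb$j] <- if (length(tb$idx) == 0L) tb$out[1L]
                 else tb$out[sum(state[tb$idx] * tb$w) + 1L]
  }
  if (length(cn$clamp_idx)) nxt[cn$clamp_idx] <- cn$clamp_val
  nxt
}

# A state consistent with the clamps, with free coordinates as given.
make_state <- function(cn, free_bits) {
  st <- integer(cn$n)
  if (length(cn$clamp_idx)) st[cn$clamp_idx] <- cn$clamp_val
  st[cn$free_idx] <- free_bits
  st
}

check_state <- function(net, state) {
  state <- as.integer(state)
  if (length(state) != length(net$nodes)) {
    stop("state has length ", length(state), "; network has ",
         length(net$nodes), " nodes", call. = FALSE)
  }
  if (!all(state %in% c(0L, 1L))) stop("state must be binary", call. = FALSE)
  state
}
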