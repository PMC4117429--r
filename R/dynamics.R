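#' Synchronous and asynchronous Boolean updates
#'
#' `step_sync()` updates every regulated node simultaneously from the
#' previous state: each node takes its logic-table output evaluated on the
#' old state, and input nodes are re-clamped to their clamp value.
#' `step_async()` performs one asynchronous sweep: the nodes are visited one
#' at a time in a fresh uniformly random permutation, each update seeing the
#' effects of the updates before it in the sweep.  A sweep updates every
#' node exactly once, so step counts remain comparable between the two
#' modes.
#'
#' @param net A [boolean_network()].
#' @param state Binary state vector in network node order.
#' @param seed Optional integer seed for the permutation (`step_async()`
#'   only); `NULL` draws from the current RNG stream.
#' @return The successor state (integer 0/1 vector).
#' @examples
#' toy <- fixture_network("TOY3")
#' step_sync(toy, c(0, 0, 1))
#' @export
step_sync <- function(net, state) {
  state <- check_state(net, state)
  compiled_step(compile_network(net), state)
}

#' @rdname step_sync
#' @export
step_async <- function(net, state, seed = NULL) {
  state <- check_state(net, state)
  cn <- compile_network(net)
  with_seed(seed, {
    order <- sample.int(cn$n)
    st <- state
    if (length(cn$clamp_idx)) st[cn$clamp_idx] <- cn$clamp_val
    by_node <- setNames(cn$tabs, vapply(cn$tabs, function(tb)
      cn$nodes[tb$j], character(1)))
    for (j in order) {
      node <- cn$nodes[j]
      tb <- by_node[[node]]
      if (is.null(tb)) next # clamped input
      st[j] <- if (length(tb$idx) == 0L) tb$out[1L]
               else tb$out[sum(st[tb$idx] * tb$w) + 1L]
    }
    st
  })
}

#' Run synchronous dynamics until the trajectory cycles
#'
#' Iterates [step_sync()] from an initial state, detecting the first
#' repeated state by hashing every visited state.  The visited sequence is
#' split into the transient (states before the cycle is entered) and the
#' cycle itself (in first-occurrence order); a fixed point is a cycle of
#' length one.
#'
#' @inheritParams step_sync
#' @param max_steps Maximum number of states to visit before giving up with
#'   a "horizon exceeded" error (synchronous dynamics on models of this
#'   class cycle far sooner; the error is never silent truncation).
#' @return An object of class `bn_trajectory` with elements `transient` and
#'   `cycle`, each a list of states.
#' @examples
#' tr <- run_to_cycle(fixture_network("TOY3"), c(0, 0, 1))
#' length(tr$cycle)
#' @export
run_to_cycle <- function(net, state, max_steps = 10000L) {
  state <- check_state(net, state)
  stopifnot(max_steps >= 1L)
  cn <- compile_network(net)
  compiled_run_to_cycle(cn, state, max_steps)
}

compiled_run_to_cycle <- function(cn, state, max_steps = 10000L) {
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  states <- vector("list", 64L)
  st <- state
  i <- 0L
  repeat {
    key <- state_key(st)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      states <- states[seq_len(i)]
      return(structure(
        list(transient = states[seq_len(prev - 1L)],
             cycle = states[prev:i]),
        class = "bn_trajectory"
      ))
    }
    i <- i + 1L
    if (i > max_steps) {
      stop("horizon exceeded: no cycle within ", max_steps, " steps",
           call. = FALSE)
    }
    if (i > length(states)) states <- c(states, vector("list", length(states)))
    states[[i]] <- st
    seen[[key]] <- i
    st <- compiled_step(cn, st)
  }
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat("<bn_trajectory> transient ", length(x$transient), " state(s), cycle ",
      length(x$cycle), " state(s)\n", sep = "")
  invisible(x)
}

#' Stochastic percentage-ON input protocol
#'
#' Instead of clamping the input nodes, each input node is set ON
#' independently at every step with a given probability, followed by one
#' synchronous update of the regulated nodes.  The activity of each node is
#' its mean state over the final measurement window; activities are also
#' discretized into three categories on the whole-percent scale:
#' 0 for 0--9%, 1 for 10--29%, and 2 for 30--100%.
#'
#' @inheritParams step_sync
#' @param input_probs Named vector of ON-probabilities, one per input node
#'   (missing inputs default to probability 0).
#' @param total_steps Number of update steps (default 1000).
#' @param window Length of the final measurement window (default 100; must
#'   not exceed `total_steps`).
#' @param init Optional initial state; defaults to all-OFF.
#' @param seed Optional integer seed.
#' @return An object of class `bn_stochastic_run`: a list with `activities`
#'   and `categories` (named numeric vectors over all nodes) and the
#'   `window`/`total_steps` used.
#' @export
stochastic_input_run <- function(net, input_probs = NULL, total_steps = 1000L,
                                 window = 100L, init = NULL, seed = NULL) {
  stopifnot(inherits(net, "boolean_network"),
            window >= 1L, window <= total_steps)
  probs <- setNames(rep(0, length(net$inputs)), net$inputs)
  if (!is.null(input_probs)) {
    stopifnot(!is.null(names(input_probs)))
    if (length(bad <- setdiff(names(input_probs), net$inputs))) {
      stop("'", bad[1L], "' is not an input node", call. = FALSE)
    }
    if (any(input_probs < 0 | input_probs > 1)) {
      stop("input probabilities must lie in [0, 1]", call. = FALSE)
    }
    probs[names(input_probs)] <- input_probs
  }
  cn <- compile_network(net)
  st <- if (is.null(init)) make_state(cn, rep(0L, length(cn$free_idx)))
        else check_state(net, init)
  with_seed(seed, {
    acc <- numeric(cn$n)
    measure_from <- total_steps - window + 1L
    for (t in seq_len(total_steps)) {
      if (length(cn$clamp_idx)) {
        st[cn$clamp_idx] <- as.integer(runif(length(cn$clamp_idx)) < probs)
      }
      nxt <- st
      for (tb in cn$tabs) {
        nxt[tb$j] <- if (length(tb$idx) == 0L) tb$out[1L]
                     else tb$out[sum(st[tb$idx] * tb$w) + 1L]
      }
      st <- nxt
      if (t >= measure_from) acc <- acc + st
    }
    activities <- setNames(acc / window, cn$nodes)
    structure(
      list(activities = activities,
           categories = activity_category(activities),
           total_steps = total_steps, window = window),
      class = "bn_stochastic_run"
    )
  })
}

#' Discretize node activities into the three output categories
#'
#' Activities (fractions ON over the measurement window) are rounded to
#' whole percent and binned: 0--9% is category 0, 10--29% category 1 and
#' 30--100% category 2.
#'
#' @param activity Numeric vector of fractions in `[0, 1]`.
#' @return Integer vector of categories (0, 1 or 2).
#' @export
activity_category <- function(activity) {
  stopifnot(all(activity >= 0 & activity <= 1))
  pct <- round(activity * 100)
  out <- integer(length(activity))
  out[pct >= 10] <- 1L
  out[pct >= 30] <- 2L
  setNames(out, names(activity))
}

#' @export
print.bn_stochastic_run <- function(x, ...) {
  cat("<bn_stochastic_run> ", x$total_steps, " steps, window ", x$window,
      "\n", sep = "")
  print(round(x$activities, 3))
  invisible(x)
}

# Full synchronous transition map over the free-node assignments (clamped
# inputs held at their clamp).  Returns a tibble of state keys.
#' Exhaustive synchronous transition map
#'
#' Enumerates every assignment of the free (non-clamped) nodes and applies
#' one synchronous step to each, returning the complete state-transition
#' map.  Feasible only for small models; used by the exact attractor
#' enumerator and by tests of dynamical equivalence after edge deletion.
#'
#' @inheritParams step_sync
#' @param max_free Safety cap on the number of free nodes (default 20).
#' @return A tibble with columns `from` and `to` (state keys over all nodes
#'   in network node order), one row per free-node assignment.
#' @export
transition_map <- function(net, max_free = 20L) {
  stopifnot(inherits(net, "boolean_network"))
  cn <- compile_network(net)
  f <- length(cn$free_idx)
  if (f > max_free) {
    stop("network has ", f, " free nodes; cap is ", max_free, call. = FALSE)
  }
  keys_from <- character(2L^f)
  keys_to <- character(2L^f)
  for (r in seq_len(2L^f) - 1L) {
    st <- make_state(cn, int_to_bits(r, f))
    keys_from[r + 1L] <- state_key(st)
    keys_to[r + 1L] <- state_key(compiled_step(cn, st))
  }
  tibble::tibble(from = keys_from, to = keys_to)
}
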