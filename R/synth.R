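# Seeded random Boolean network generator and the canonical hand-built
# fixtures used throughout the test-bed.

#' Generate a random Boolean network
#'
#' Builds a seeded random Boolean network in the model class of large
#' signaling models: a set of clamped input nodes, regulated nodes whose
#' regulators are drawn from a configurable in-degree distribution, and
#' truth-table rows drawn i.i.d. Bernoulli with a given ON-bias.  Feedback
#' loops of prescribed lengths can be planted first, wired with copy logic
#' (each loop node copies its predecessor), so that a sustained limit cycle
#' exists and the dynamics do not collapse to the all-OFF fixed point --
#' random-bias tables alone frequently do.
#'
#' @param n_nodes Total node count.
#' @param n_inputs Number of clamped input nodes (`< n_nodes`).
#' @param degree In-degree distribution for regulated nodes outside planted
#'   loops: `list(fixed = k)`, `list(poisson = lambda)` or
#'   `list(powerlaw = alpha)` (discrete inverse-CDF on `1..n_nodes - 1`).
#' @param bias Probability that a truth-table row outputs 1.
#' @param plant List of `c(length, count)` pairs of feedback loops to plant
#'   among the regulated nodes, e.g. `list(c(3, 1))` for one 3-loop.
#' @param seed Integer seed; the same seed reproduces the network
#'   bit-identically, tables included.
#' @return A [boolean_network()].
#' @examples
#' net <- generate_network(10, n_inputs = 2, degree = list(poisson = 2),
#'                         plant = list(c(3, 1)), seed = 7)
#' net
#' @export
generate_network <- function(n_nodes, n_inputs = 1L,
                             degree = list(poisson = 2),
                             bias = 0.5, plant = list(), seed = NULL) {
  stopifnot(n_inputs >= 0L, n_inputs < n_nodes, bias >= 0, bias <= 1)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  inputs <- head(nodes, n_inputs)
  regulated <- setdiff(nodes, inputs)
  planted_total <- sum(vapply(plant, function(p) p[1] * p[2], numeric(1)))
  if (planted_total > length(regulated)) {
    stop("planted loops need ", planted_total,
         " regulated nodes; only ", length(regulated), " available",
         call. = FALSE)
  }
  with_seed(seed, {
    tables <- list()
    pool <- regulated
    # planted loops first: copy logic guarantees the cycle survives as a
    # dynamical limit cycle
    for (p in plant) {
      len <- p[1]
      for (rep in seq_len(p[2])) {
        loop_nodes <- pool[seq_len(len)]
        pool <- pool[-seq_len(len)]
        for (i in seq_len(len)) {
          pred <- loop_nodes[if (i == 1L) len else i - 1L]
          tables[[loop_nodes[i]]] <-
            logic_table(loop_nodes[i], pred, c(0L, 1L))
        }
      }
    }
    for (v in pool) {
      k <- draw_in_degree(degree, n_nodes - 1L)
      regs <- if (k > 0L) sample(nodes, k) else character(0)
      # no edges into input nodes exist by construction (inputs have no
      # tables); regulators may be any node including v itself
      outputs <- as.integer(runif(2L^k) < bias)
      tables[[v]] <- logic_table(v, regs, outputs)
    }
    boolean_network(unname(tables), inputs = inputs, nodes = nodes)
  })
}

draw_in_degree <- function(degree, kmax) {
  stopifnot(is.list(degree), length(degree) == 1L)
  kind <- names(degree)
  val <- degree[[1L]]
  k <- switch(kind,
    fixed = as.integer(val),
    poisson = stats::rpois(1L, val),
    powerlaw = {
      support <- seq_len(kmax)
      probs <- support^(-val)
      sample(support, 1L, prob = probs / sum(probs))
    },
    stop("unknown degree distribution '", kind, "'", call. = FALSE)
  )
  max(0L, min(k, kmax))
}

#' Canonical test fixtures
#'
#' Small hand-built networks used throughout the documentation and tests:
#'
#' * `TOY3`: nodes A (input, clamped 0), B and C with `B = A OR C` and
#'   `C = B`.  Its landscape under A = 0 has fixed points `000` and `011`
#'   and the 2-cycle `{001, 010}`; its evolvable core is `{(C,B), (B,C)}`.
#' * `TRIAD`: three copy gates in a directed cycle; two fixed points and
#'   two 3-cycles with basins 1, 1, 3, 3.
#' * `FFWD5`: a feed-forward chain of copy gates behind one clamped input;
#'   acyclic, so a single fixed-point attractor.
#' * `REDUNDANT4`: input I, a node X regulated by I and (fictitiously) by
#'   Y, and a copy 2-cycle Y <-> Z; the edge (Y, X) is locally redundant
#'   while the 2-cycle edges are dynamically essential for the primary
#'   attractor.
#'
#' @param name One of `"TOY3"`, `"TRIAD"`, `"FFWD5"`, `"REDUNDANT4"`.
#' @return A [boolean_network()].
#' @export
fixture_network <- function(name = c("TOY3", "TRIAD", "FFWD5",
                                     "REDUNDANT4")) {
  name <- match.arg(name)
  switch(name,
    TOY3 = boolean_network(
      tables = list(
        logic_table("B", c("A", "C"), c(0L, 1L, 1L, 1L)),
        logic_table("C", "B", c(0L, 1L))
      ),
      inputs = "A", nodes = c("A", "B", "C")
    ),
    TRIAD = boolean_network(
      tables = list(
        logic_table("X", "Z", c(0L, 1L)),
        logic_table("Y", "X", c(0L, 1L)),
        logic_table("Z", "Y", c(0L, 1L))
      ),
      nodes = c("X", "Y", "Z")
    ),
    FFWD5 = boolean_network(
      tables = list(
        logic_table("B", "A", c(0L, 1L)),
        logic_table("C", "B", c(0L, 1L)),
        logic_table("D", "C", c(0L, 1L)),
        logic_table("E", "D", c(0L, 1L))
      ),
      inputs = "A", nodes = c("A", "B", "C", "D", "E")
    ),
    REDUNDANT4 = boolean_network(
      tables = list(
        # X <- f(I, Y) = I: the edge (Y, X) is fictitious/redundant
        logic_table("X", c("I", "Y"), c(0L, 0L, 1L, 1L)),
        logic_table("Y", "Z", c(0L, 1L)),
        logic_table("Z", "Y", c(0L, 1L))
      ),
      inputs = "I", nodes = c("I", "X", "Y", "Z")
    )
  )
}
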