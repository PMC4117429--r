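---
title: "Decomposing Boolean signaling networks by their attractor landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing Boolean signaling networks by their attractor landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolcarve)
```

## The model class

A Boolean network here is a directed graph together with one logic table
per regulated node.  A network state assigns 0/1 to every node; the
synchronous step replaces each regulated node's value with its table output
on the previous state.  Nodes with no incoming edge are treated as external
inputs (ligands) and are *clamped*: re-fixed at every step, OFF by default,
so that the simulated dynamics are those of the unstimulated system.  Clamp
values can be switched per input (`set_clamp()`) to reproduce stimulated
conditions, and a stochastic protocol (`stochastic_input_run()`) replaces
clamping by independent Bernoulli draws per input per step, measuring each
node's fraction ON over a final window (defaults: 1000 steps, window 100)
and discretizing it into three categories on the whole-percent scale (0-9%,
10-29%, 30-100%).

Because the state space is finite and the synchronous map deterministic,
every trajectory enters a cycle; `run_to_cycle()` detects the first repeat
by hashing visited states, which is exact — the `max_steps` horizon
(default 10,000) only bounds memory and raises an explicit error rather
than truncating silently.  An asynchronous variant is provided as a
random-permutation sweep: each step visits all nodes once in a fresh
uniform order.  The update scheduling of asynchronous Boolean models is a
genuine modeling choice (single-node-per-step schemes exist too); the sweep
was chosen so that step counts remain comparable with synchronous runs.

## Attractor landscapes

`find_attractors()` estimates the landscape from `n_samples` initial states
drawn uniformly over the free-node assignments.  Attractors are
deduplicated by a canonical form: the rotation of the cyclic state sequence
that is lexicographically minimal.  Identity is *exact equality of the
canonical full-dimension sequence* — the strictest reading of "the same
attractor", available here because edge deletion never changes the node
set.  The primary attractor maximizes the basin count, with ties broken by
the lexicographically smallest canonical sequence so that results are
platform-independent.

`enumerate_attractors()` is the exact oracle for the feasible regime: it
traverses every free assignment (capped at 20 free nodes) and returns exact
basin sizes.  The test suite holds the sampled estimator to exact equality
with this oracle when the sample covers every free state, and to 3 binomial
standard errors when sampling randomly.  For models whose state count is
astronomically large the sampled landscape is the only option; sample sizes
of 10^4 are a practical compromise at the ~140-node scale, where enlarging
the sample 10-100x leaves the estimated relative basin sizes essentially
unchanged.

`sample_basin_states()` performs rejection sampling from one attractor's
basin and aborts explicitly when a probe indicates an acceptance rate below
`1e-3` — silently looping on a negligible basin would otherwise be the
failure mode.

## The decomposition algorithm

`decompose()` implements the edge-knockout decomposition:

1. estimate the landscape, identify the primary attractor;
2. sample `n_samples` basin states *once* and reuse them for every later
   test (re-sampling per deletion would let preservation drift);
3. delete all insignificant edges — `(u, v)` is insignificant when fixing
   `u` to 0 and to 1 yields identical reduced tables for `v`, so deletion
   provably leaves the whole transition map unchanged;
4. screen remaining edges: a candidate is an edge whose single deletion
   keeps every sampled basin state converging to the original primary
   attractor;
5. consume the candidate set in uniformly random order, re-testing each
   candidate against the *current* reduced network before deleting it;
   failed candidates are discarded;
6. when the set is exhausted, rebuild it from scratch on the current
   network; terminate when a rebuild finds nothing deletable.

The rebuild-on-exhaustion policy covers both readings of "repeat until the
network cannot be reduced any more": an edge that failed earlier may be
re-tried after later deletions, because rebuilding re-screens every
remaining edge.

Two conventions deserve flagging:

* **Deletion semantics.** Deleting `(u, v)` replaces `v`'s table by its
  reduced table with `u` fixed — at 0 by default, matching the global
  inputs-OFF nominal condition.  The fixed value is configurable
  (`delete_value = 1`); for edges far from the clamped inputs the two
  choices can genuinely differ, and nothing in the model class dictates
  one.
* **Preservation threshold.** "Preserved" means *every* sampled basin
  state reaches the exact original primary cycle (`min_fraction = 1`).  A
  tolerance knob exists but defaults to the strictest reading; a horizon
  overrun during a test counts as not preserved.

Randomness enters through exactly two named seeds — `seed_init` for the
landscape/basin sampling and `seed_order` for the deletion order — the two
robustness axes on which stability across reruns should be (and in the test
suite is) checked.  The result partitions the edge set; `provenance`
records why each neighbor edge left (`insignificant` vs
`candidate_deleted`), and `verify_decomposition()` re-checks the
definitional contracts from scratch: the core alone preserves the primary
attractor, no single core edge is deletable (minimality), and
core/neighbor partition the edges.

Node scores follow directly: a node's evolvability is the fraction of its
incident (in plus out) edges in the core, robustness the complement;
isolated nodes carry no score.

`perturbation_novelty()` quantifies the flip side of the core: deleting
core edges one at a time and rerunning the basin states yields non-primary
attractors, and the fraction of those absent from the original attractor
list measures how readily single-edge knockouts *create* genuinely new
attractors — the bridge between "changes the primary attractor" and the
alternative notion of evolvability as emergence of new attractors.

## Topological null models

Sub-network statistics are compared against two ensembles: *random
deletion* (remove `m` uniform edges from the full network — the null for an
evolvable core) and *random selection* (keep `m` uniform edges — the null
for a robust neighbor), both retaining the node set.  Statistics: counts of
simple directed cycles of length 1, 2, 3 (a 2-cycle counts once per node
pair; a 3-node set with both orientations counts twice, once per directed
traversal); degree heterogeneity = population variance of the total degree
distribution over its mean; characteristic path length = mean *directed*
shortest-path length over reachable ordered pairs, with unreachable pairs
excluded rather than imputed (the cited definition is silent; directed
distances fit signaling flow, and the choice is switchable by supplying an
undirected edge table); weakly connected components over edge-touched nodes
(a regulator disconnected in the sub-network still belongs to its module,
hence *weak*; edge-free nodes do not count as components).

The observed statistic is tested against the null replicates one-sidedly.
With a single observed sub-network this is the one-sample t test of the
null values against the observed value (a two-sample test is not defined
for one observation); when several observed replicates are supplied via
`observed_value` the Welch unequal-variance two-sample test is used.  A
degenerate null (zero variance) is floored and flagged rather than
producing NaN.

One cautionary note encoded in the tests: heterogeneity is *not* monotone
under adding an edge at the hub, because the new edge also raises the
far endpoint's degree; only adding degree solely at the maximal-degree node
(e.g. a self-loop) provably never lowers variance/mean.

## Canalization and redundant links

A function is canalizing when one input value alone forces the output.
`canalizing_inputs()` returns all verified (input, value, forced output)
triples.  Link redundancy is operationalized as prime-implicant
non-essentiality: edge `(u, v)` is redundant when `u` appears in no
implicant of the minimal two-level cover of `v`'s function nor of its
complement, computed by exact Quine-McCluskey minimization (no heuristic
minimizers; table widths in this model class are small).  Every fictitious
input (identical reduced tables) is redundant under this criterion.  The
notion is purely local — independent of clamps, dynamics and seeds — which
is exactly how it differs from robust-neighbor membership: neighbor edges
are identified through global dynamics and need not be locally redundant.
The literature's redundancy notion is defined largely by illustration, and
alternative formalizations (e.g. context-dependent wildcard schemata) would
classify partially redundant inputs differently; counts of redundant links
therefore depend on this choice.

## Gene-level enrichment

`gene_scores()` maps node scores to genes (a gene's score is the mean over
its nodes; nodes mapping to several genes contribute to each — the natural
aggregation when the node-gene map is many-to-many).  Normalized group
scores divide a group's mean by the universe mean, making 1.0 the neutral
value and the measure scale-invariant.  `permutation_test()` compares a
group's mean score against random same-size gene sets drawn without
replacement, with the finite-sample estimator
`p = (1 + #{permuted >= observed}) / (n_perm + 1)`, so p never drops below
`1/(n_perm + 1)`; 100,000 permutations is the default.  Pearson
correlations with numeric gene properties (dN/dS evolutionary rate, species
broadness) drop missing values pairwise and report the effective n.  All
annotations are consumed from a user-supplied TSV; no database retrieval is
attempted.

## The synthetic generator

`generate_network()` emulates the model class: clamped inputs, regulators
drawn per an in-degree distribution (fixed / Poisson / truncated power-law
via inverse CDF), i.i.d. Bernoulli truth-table rows.  Planted feedback
loops are wired first with copy logic, because pure random-bias tables
frequently collapse to the all-OFF fixed point and would leave the
decomposition with a trivial primary attractor; a copy loop guarantees a
sustained limit cycle.  Everything is driven by one seed and reproduces
bit-identically.

What the generator does *not* emulate: the curated logic (strong
canalization, signed activation/inhibition structure) and the heavy-tailed,
correlated degree sequence of real signaling maps.  Green tests on
generated networks therefore certify the algorithmic contracts — oracle
equivalence, soundness, minimality, calibration — not biological
conclusions about any particular curated model, which enters only as a
user-supplied file.

## Numerical and scale choices

Truth-table rows are indexed by reading the input tuple as a binary number,
first listed input most significant — fixed once so that files round-trip
bit-exactly.  Node ids compare case-sensitively and all tie-breaks
(deterministic edge iteration, primary-attractor ties) use lexicographic
order.  State hashing is exact (string keys), so cycle detection has no
tolerance parameters.

Problem sizes in the tests and the acceptance script — networks of 8-18
nodes, landscapes from a few hundred to a few thousand initial states,
100-replicate null ensembles, 10^5 permutations — were chosen so the exact
enumerator stays available as an oracle alongside every sampled estimate;
all operations scale to the ~140-node, 10^4-sample regime of real curated
models, where the decomposition's repeated trajectory tests dominate the
cost and parallelize naturally per candidate edge.  Two implementation
details keep the repeated preservation tests cheap without changing their
outcome: duplicate sampled basin states are tested once, and trajectory
classifications are memoized within a candidate network, so overlapping
trajectories short-circuit.

## Known limitations

* Attractor identity is exact sequence equality; near-identical attractors
  (one node flipped in one state) count as different, which is what makes
  the core minimal but also makes preservation brittle to any tolerance a
  user might have wanted.
* The candidate re-test order is uniformly random; core *size* is stable
  across deletion seeds in practice, but core *membership* of individually
  marginal edges can vary — report across several `seed_order` values for
  membership claims.
* `enumerate_attractors()` and `transition_map()` are capped at 20 free
  nodes by design; beyond that only sampled estimates are available.
* The asynchronous mode supports stepping and reachability checks, not
  basin estimation: basins are not well defined under stochastic update
  order.
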