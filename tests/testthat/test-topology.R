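triad <- fixture_network("TRIAD")

test_that("feedback counts match exhaustive cycle enumeration", {
  expect_equal(count_feedbacks(triad, 1), 0)
  expect_equal(count_feedbacks(triad, 2), 0)
  expect_equal(count_feedbacks(triad, 3), 1)

  two <- tibble::tibble(source = c("u", "v"), target = c("v", "u"))
  expect_equal(count_feedbacks(two, 1), 0)
  expect_equal(count_feedbacks(two, 2), 1)
  expect_equal(count_feedbacks(two, 3), 0)

  k3 <- expand.grid(source = c("a", "b", "c"), target = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  expect_equal(count_feedbacks(k3, 1), 3)
  expect_equal(count_feedbacks(k3, 2), 3)
  expect_equal(count_feedbacks(k3, 3), 2)

  for (s in 1:12) {
    g <- random_digraph(6, 0.3, seed = 300 + s)
    for (k in 1:3) {
      expect_equal(count_feedbacks(g$edges, k),
                   oracle_cycle_count(g$edges, g$nodes, k),
                   label = paste("seed", s, "k", k))
    }
  }
  expect_error(count_feedbacks(triad, 4), "k")
})

test_that("edge deletion never increases any feedback count", {
  for (s in 1:5) {
    g <- random_digraph(7, 0.35, seed = 500 + s)
    full <- vapply(1:3, function(k) count_feedbacks(g$edges, k), numeric(1))
    sub <- random_deletion_subnetwork(subnetwork(g$edges, g$nodes), 5,
                                      seed = s)
    subc <- vapply(1:3, function(k) count_feedbacks(sub, k), numeric(1))
    expect_true(all(subc <= full))
  }
})

test_that("degree heterogeneity matches hand computations", {
  expect_equal(degree_heterogeneity(triad), 0) # 2-regular
  star <- tibble::tibble(source = rep("h", 4),
                         target = c("a", "b", "c", "d"))
  expect_equal(degree_heterogeneity(star), 0.9) # degrees 4,1,1,1,1
  empty <- subnetwork(tibble::tibble(source = character(),
                                     target = character()),
                      nodes = c("a", "b"))
  expect_error(degree_heterogeneity(empty), "isolated")
})

test_that("adding degree only at the hub never decreases heterogeneity", {
  # raising the maximal degree alone cannot lower var/mean (Bhatia-Davis)
  for (s in 1:8) {
    g <- random_digraph(7, 0.25, seed = 700 + s, self_loops = FALSE)
    if (nrow(g$edges) < 2) next
    parts <- boolcarve:::as_graph_parts(subnetwork(g$edges, g$nodes))
    deg <- boolcarve:::node_degrees(parts)
    hub <- names(which.max(deg))
    grown <- dplyr::bind_rows(g$edges,
                              tibble::tibble(source = hub, target = hub))
    expect_gte(degree_heterogeneity(subnetwork(grown, g$nodes)),
               degree_heterogeneity(subnetwork(g$edges, g$nodes)))
    # oracle recomputation from raw degrees
    d2 <- boolcarve:::node_degrees(
      boolcarve:::as_graph_parts(subnetwork(grown, g$nodes)))
    expect_equal(degree_heterogeneity(subnetwork(grown, g$nodes)),
                 mean((d2 - mean(d2))^2) / mean(d2))
  }
})

test_that("characteristic path length averages finite directed distances", {
  expect_equal(characteristic_path_length(triad), 1.5) # (1+2)*3/6
  single <- tibble::tibble(source = "u", target = "v")
  expect_equal(characteristic_path_length(single), 1.0)
  k4 <- expand.grid(source = paste0("n", 1:4), target = paste0("n", 1:4),
                    stringsAsFactors = FALSE)
  k4 <- k4[k4$source != k4$target, ]
  expect_equal(characteristic_path_length(k4), 1.0)
  expect_identical(characteristic_path_length(triad),
                   characteristic_path_length(triad)) # deterministic
  none <- subnetwork(tibble::tibble(source = character(),
                                    target = character()), nodes = "a")
  expect_error(characteristic_path_length(none), "reachable")
})

test_that("weak components count edge-touched nodes only", {
  two_cycles <- tibble::tibble(source = c("a", "b", "c", "d"),
                               target = c("b", "a", "d", "c"))
  expect_equal(connected_components(two_cycles), 2)
  expect_equal(connected_components(triad), 1)
  toy_neighbor <- subnetwork(tibble::tibble(source = "A", target = "B"),
                             nodes = c("A", "B", "C"))
  expect_equal(connected_components(toy_neighbor), 1) # C is isolated
  expect_equal(connected_components(
    subnetwork(tibble::tibble(source = character(), target = character()),
               nodes = c("x", "y"))), 0)
})

test_that("null sub-network samplers are uniform and size-exact", {
  net <- fixture_network("TOY3")
  expect_equal(random_deletion_subnetwork(net, 0, seed = 1)$edges,
               network_edges(net))
  expect_equal(random_selection_subnetwork(net, n_edges(net),
                                           seed = 1)$edges,
               network_edges(net))
  expect_error(random_deletion_subnetwork(net, 99), "m")

  g <- tibble::tibble(source = c("a", "b", "c"), target = c("b", "c", "a"))
  picks <- vapply(1:3000, function(s) {
    sub <- random_selection_subnetwork(subnetwork(g), 1, seed = s)
    paste(sub$edges$source, sub$edges$target)
  }, character(1))
  freq <- table(picks) / 3000
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 3000)))
})

test_that("planted feedback structure separates from deletion nulls", {
  net <- generate_network(24, n_inputs = 1, degree = list(poisson = 1.5),
                          plant = list(c(3, 5)), seed = 123)
  ed <- network_edges(net)
  # observed sub-network: exactly the planted copy-loop edges
  loops <- ed[ed$source %in% sprintf("n%02d", 2:16) &
                ed$target %in% sprintf("n%02d", 2:16), ]
  loops <- loops[vapply(seq_len(nrow(loops)), function(i) {
    tb <- net$tables[[loops$target[i]]]
    length(tb$inputs) == 1
  }, logical(1)), ]
  obs <- subnetwork(loops, net$nodes)
  expect_equal(count_feedbacks(obs, 3), 5)
  nc <- null_comparison(obs, net, statistic = "three_node_feedbacks",
                        replicates = 100, direction = "greater",
                        null = "deletion", seed = 11)
  expect_lt(nc$p_value, 0.05)
  expect_equal(nc$m, n_edges(net) - nrow(loops))
})

test_that("a statistic at the null mean yields p near one half", {
  net <- generate_network(15, n_inputs = 1, degree = list(poisson = 2),
                          seed = 31)
  probe <- null_comparison(network_edges(net), net, m = 8,
                           statistic = "degree_heterogeneity",
                           replicates = 100, seed = 6)
  centered <- null_comparison(network_edges(net), net, m = 8,
                              statistic = "degree_heterogeneity",
                              replicates = 100, seed = 6,
                              observed_value = mean(probe$null_values))
  expect_gt(centered$p_value, 0.4)
  expect_lt(centered$p_value, 0.6)
})

test_that("degenerate null variance is floored and flagged", {
  net <- fixture_network("TRIAD")
  nc <- null_comparison(network_edges(net), net, m = 0,
                        statistic = "three_node_feedbacks",
                        replicates = 2, seed = 1)
  expect_true(nc$degenerate_null)
  expect_true(nc$p_value > 0 && nc$p_value <= 1)
})

test_that("null ensembles are exchangeable across seeds", {
  net <- generate_network(15, n_inputs = 1, degree = list(poisson = 2),
                          seed = 77)
  n1 <- null_comparison(network_edges(net), net, m = 8,
                        statistic = "degree_heterogeneity",
                        replicates = 100, seed = 101)
  n2 <- null_comparison(network_edges(net), net, m = 8,
                        statistic = "degree_heterogeneity",
                        replicates = 100, seed = 202)
  ks <- suppressWarnings(stats::ks.test(n1$null_values, n2$null_values))
  expect_gt(ks$p.value, 0.01)
})

test_that("neighbor-link ratios per degree bin follow incidence counting", {
  toy <- fixture_network("TOY3")
  dec <- decompose(toy, n_samples = 30, seed_init = 1, seed_order = 2)
  # degrees: A=1, C=2, B=3; neighbor = {(A,B)}
  ratios <- degree_bin_neighbor_ratio(
    toy, dec, bins = list(low = 1L, mid = 2L, high = 3L))
  expect_equal(ratios$ratio[ratios$bin == "low"], 1)    # A: 1/1
  expect_equal(ratios$ratio[ratios$bin == "mid"], 0)    # C: 0/2
  expect_equal(ratios$ratio[ratios$bin == "high"], 1 / 3) # B: 1/3

  all_core <- dec
  all_core$provenance$class <- "core"
  r2 <- degree_bin_neighbor_ratio(toy, all_core,
                                  bins = list(all = 1:10))
  expect_equal(r2$ratio, 0)
  all_nb <- dec
  all_nb$provenance$class <- "neighbor"
  r3 <- degree_bin_neighbor_ratio(toy, all_nb, bins = list(all = 1:10))
  expect_equal(r3$ratio, 1)
  r4 <- degree_bin_neighbor_ratio(toy, dec, bins = list(ghost = 9L))
  expect_true(is.na(r4$ratio))
})
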