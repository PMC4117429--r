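test_that("canalizing triples are detected and verify exhaustively", {
  or2 <- logic_table("f", c("X", "Y"), c(0L, 1L, 1L, 1L))
  got <- canalizing_inputs(or2)
  expect_equal(nrow(got), 2)
  expect_setequal(got$input, c("X", "Y"))
  expect_true(all(got$value == 1 & got$output == 1))

  xor <- logic_table("f", c("X", "Y"), c(0L, 1L, 1L, 0L))
  expect_equal(nrow(canalizing_inputs(xor)), 0)

  and_or <- logic_table("f", c("A", "B", "C"),
                        c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L)) # A AND (B OR C)
  got3 <- canalizing_inputs(and_or)
  expect_equal(nrow(got3), 1)
  expect_equal(got3$input, "A")
  expect_equal(got3$value, 0L)
  expect_equal(got3$output, 0L)

  # self-check every claim against the full table
  set.seed(17)
  for (trial in 1:15) {
    k <- sample(2:4, 1)
    tb <- logic_table("f", paste0("x", 1:k), as.integer(runif(2^k) < 0.4))
    claims <- canalizing_inputs(tb)
    rows <- seq_len(2^k) - 1
    for (i in seq_len(nrow(claims))) {
      pos <- match(claims$input[i], tb$inputs)
      bit <- bitwAnd(rows %/% 2^(k - pos), 1)
      expect_true(all(tb$outputs[bit == claims$value[i]] ==
                        claims$output[i]))
    }
  }
})

test_that("prime implicants and minimal covers satisfy their definitions", {
  set.seed(23)
  covers_fn <- function(imp, m) {
    bitwAnd(bitwXor(imp$bits, m), bitwNot(imp$mask)) == 0
  }
  for (trial in 1:20) {
    k <- sample(2:4, 1)
    outputs <- as.integer(runif(2^k) < 0.5)
    minterms <- which(outputs == 1L) - 1L
    primes <- boolcarve:::qm_prime_implicants(minterms, k)
    # every prime is an implicant of the ON-set
    for (p in primes) {
      member <- vapply(0:(2^k - 1), function(m) covers_fn(p, m), logical(1))
      expect_true(all((which(member) - 1) %in% minterms))
      # and maximal: freeing any fixed bit breaks implicant-hood
      fixed_bits <- which(boolcarve:::int_to_bits(p$mask, k) == 0)
      for (b in fixed_bits) {
        wider <- list(bits = bitwAnd(p$bits, bitwNot(2^(k - b))),
                      mask = bitwOr(p$mask, 2^(k - b)))
        member_w <- vapply(0:(2^k - 1), function(m) covers_fn(wider, m),
                           logical(1))
        expect_false(all((which(member_w) - 1) %in% minterms))
      }
    }
    cover <- boolcarve:::qm_minimal_cover(primes, minterms)
    if (length(minterms)) {
      covered <- vapply(minterms, function(m) {
        any(vapply(cover, covers_fn, logical(1), m = m))
      }, logical(1))
      expect_true(all(covered))
      # minimum cardinality, by brute force over prime subsets
      if (length(primes) <= 10) {
        best <- length(primes)
        for (size in seq_along(primes)) {
          found <- FALSE
          for (cb in combn(seq_along(primes), size, simplify = FALSE)) {
            ok <- all(vapply(minterms, function(m) {
              any(vapply(primes[cb], covers_fn, logical(1), m = m))
            }, logical(1)))
            if (ok) { found <- TRUE; break }
          }
          if (found) { best <- size; break }
        }
        expect_equal(length(cover), best)
      }
    }
  }
})

test_that("redundant inputs are exactly those absent from minimal covers", {
  expect_equal(redundant_inputs(logic_table("C", c("A", "B"),
                                            c(0L, 0L, 1L, 1L))), "B")
  # A OR (A AND B) is extensionally A; B is redundant
  net <- parse_network("C = A | (A & B)", "expr")
  expect_equal(redundant_inputs(net$tables$C), "B")
  xor <- logic_table("f", c("X", "Y"), c(0L, 1L, 1L, 0L))
  expect_length(redundant_inputs(xor), 0)
  const <- logic_table("f", c("X", "Y"), rep(1L, 4))
  expect_setequal(redundant_inputs(const), c("X", "Y"))

  # every planted fictitious input is reported redundant
  set.seed(29)
  for (trial in 1:10) {
    k <- sample(2:4, 1)
    inner <- as.integer(runif(2^(k - 1)) < 0.5)
    tb <- logic_table("f", paste0("x", 1:k), rep(inner, 2)) # x1 fictitious
    expect_true("x1" %in% redundant_inputs(tb))
  }
})

test_that("redundant links are local: independent of clamps and dynamics", {
  red4 <- fixture_network("REDUNDANT4")
  red <- redundant_links(red4)
  expect_equal(nrow(red), 1)
  expect_equal(paste(red$source, red$target), "Y X")
  expect_equal(redundant_links(set_clamp(red4, I = 1)), red)
  expect_equal(nrow(redundant_links(fixture_network("TOY3"))), 0)
})

test_that("redundant links intersect the decomposition as computed sets", {
  toy <- fixture_network("TOY3")
  dec_toy <- decompose(toy, n_samples = 30, seed_init = 1, seed_order = 2)
  cmp0 <- compare_redundant_vs_decomposition(toy, dec_toy)
  expect_equal(unlist(cmp0), c(n_redundant = 0, n_redundant_core = 0,
                               n_redundant_neighbor = 0))

  red4 <- fixture_network("REDUNDANT4")
  dec <- decompose(red4, n_samples = 40, seed_init = 1, seed_order = 2)
  expect_setequal(paste(dec$core_edges$source, dec$core_edges$target),
                  c("Y Z", "Z Y"))
  cmp <- compare_redundant_vs_decomposition(red4, dec)
  expect_equal(cmp$n_redundant, 1)
  expect_equal(cmp$n_redundant_core, 0)
  expect_equal(cmp$n_redundant_neighbor, 1)

  # a hand-built partition with the redundant edge kept in the core
  forced <- dec
  forced$core_edges <- dplyr::bind_rows(
    dec$core_edges, tibble::tibble(source = "Y", target = "X"))
  cmp2 <- compare_redundant_vs_decomposition(red4, forced)
  expect_equal(cmp2$n_redundant_core, 1)
})
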