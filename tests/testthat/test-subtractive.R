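test_that("delta follows the normalized coverage-change formula", {
  expect_identical(compute_delta(10, 10), 0)
  expect_identical(compute_delta(10, 2), -0.8)
  expect_identical(compute_delta(2, 10), 0.8)
  expect_error(compute_delta(0, 5), "positive")
  expect_error(compute_delta(5, -1), "positive")
})

test_that("delta is bounded, sign-correct and antisymmetric", {
  set.seed(123)
  a <- runif(1e4, 1e-3, 1e3)
  b <- runif(1e4, 1e-3, 1e3)
  d <- compute_delta(a, b)
  expect_true(all(d >= -1 & d <= 1))
  expect_true(all(sign(d) == sign(b - a)))
  expect_equal(compute_delta(b, a), -d)
})

test_that("the minimal node closest to the path end is selected", {
  expect_equal(select_min_node(c(5, 10, 5)), 3L)
  expect_equal(select_min_node(8), 1L)
  expect_equal(select_min_node(c(3, 2, 4)), 2L)
  expect_error(select_min_node(numeric(0)), "empty")
})

test_that("variant counts rise into shared regions and fall back", {
  expect_equal(estimate_variant_counts(c(10, 10, 10), 0.8), c(1, 1, 1))
  expect_equal(estimate_variant_counts(c(10, 10, 30, 30, 10, 8), 0.4),
               c(1, 1, 2, 2, 1, 1))
  expect_equal(estimate_variant_counts(c(5, 10, 5), 0.4), c(1, 2, 1))
  # threshold comparisons are strict: delta == delta_sw does not trigger
  expect_equal(estimate_variant_counts(c(5, 10, 5), 0.5), c(1, 1, 1))
})

test_that("the literal sign pairing is exposed and differs", {
  cov <- c(10, 10, 30, 30, 10, 8)
  default_counts <- estimate_variant_counts(cov, 0.4)
  printed_counts <- estimate_variant_counts(cov, 0.4, as_printed = TRUE)
  expect_false(identical(default_counts, printed_counts))
  # under the literal pairing the low-coverage flank gains the variants
  expect_equal(printed_counts, c(2, 2, 1, 1, 1, 1))
})

test_that("subtraction zeroes unique nodes, interpolates shared ones", {
  expect_equal(subtraction_amounts(c(10, 10, 10), c(1, 1, 1)),
               c(10, 10, 10))
  cov <- c(10, 10, 30, 30, 10, 8)
  amt <- subtraction_amounts(cov, c(1, 1, 2, 2, 1, 1))
  expect_equal(cov - amt, c(0, 0, 20, 20, 0, 0))
  cov2 <- c(10, 30, 30, 20)
  amt2 <- subtraction_amounts(cov2, c(1, 2, 2, 1))
  expect_equal(cov2 - amt2, c(0, 30 - (10 + 10 / 3), 30 - (10 + 20 / 3), 0),
               tolerance = 1e-12)
})

test_that("one-sided interpolation extends the available side", {
  # no count-1 node to the right: left coverage used as a constant
  amt <- subtraction_amounts(c(10, 30, 40), c(1, 2, 2))
  expect_equal(amt, c(10, 10, 10))
})

test_that("graph subtraction matches the pure computation", {
  ts <- two_strain_small()
  g <- build_graph(ts$reads, ts$k)
  seed <- component_scan(g, g$kmers[which.max(g$cov)])$seed
  ct <- walk_max_coverage(g, seed, min_coverage = 2)
  before <- g$cov[match(ct$kmers, g$kmers)]
  info <- subtract_path_coverage(g, ct, delta_sw = 0.4)
  after <- g$cov[match(ct$kmers, g$kmers)]
  expect_equal(after, pmax(before - info$amounts, 0))
  expect_true(all(after[info$counts == 1] == 0))
  expect_true(all(after[info$counts > 1] > 0))
  expect_true(all(g$cov >= 0))
})

test_that("the max-coverage walk ignores bubbles", {
  # MC routes through the 4+7 bubble; SW must take the straight 10 branch
  fx <- bubble_graph(10, 4, 7)
  mc <- choose_branch_mc(fx$graph, fx$branch_index, fx$branch_orient, 2, 64)
  sw <- straingraph:::choose_branch_greedy(fx$graph, fx$branch_index,
                                           fx$branch_orient, 2)
  expect_equal(mc$base, "G")
  expect_equal(sw$base, "A")
  expect_equal(sw$coverage, 10)
})

test_that("walks stop when no branch meets the floor", {
  fx <- bubble_graph(3, 1, 1)  # arms below a floor of 2
  ch <- straingraph:::choose_branch_greedy(fx$graph, fx$branch_index,
                                           fx$branch_orient, 2)
  expect_equal(ch$base, "A")  # only the straight branch qualifies
  ch2 <- straingraph:::choose_branch_greedy(fx$graph, fx$branch_index,
                                            fx$branch_orient, 4)
  expect_null(ch2)
})

test_that("a single linear genome is fully subtracted into one contig", {
  s <- random_genome(120, seed = 101, distinct_k = 15)
  g <- build_graph(rep(s, 5), 15)
  contigs <- assemble_sw(g, min_coverage = 2, delta_sw = 0.8)
  expect_equal(length(contigs), 1L)
  expect_true(contigs[[1L]]$sequence %in% c(s, revcomp(s)))
  expect_true(all(g$cov[g$alive] == 0))
})

test_that("an empty graph yields no contigs", {
  g <- suppressWarnings(build_graph(character(0), 15))
  expect_equal(length(assemble_sw(g)), 0L)
})

test_that("shared cores are emitted once per strain variant", {
  ts <- two_strain_small()
  g <- build_graph(ts$reads, ts$k)
  contigs <- assemble_sw(g, min_coverage = 2, delta_sw = 0.4)
  expect_gte(length(contigs), 2L)
  seqs <- vapply(contigs, `[[`, character(1), "sequence")
  core_hits <- sum(vapply(seqs, function(s) {
    grepl(ts$core, s, fixed = TRUE) || grepl(ts$core, revcomp(s),
                                             fixed = TRUE)
  }, logical(1)))
  expect_gte(core_hits, 2L)
  ev <- evaluate_assembly(seqs, c(ts$sA, ts$sB), ts$k)
  expect_true(all(ev$genome_fraction == 100))
  expect_true(all(g$cov >= 0))
})

test_that("the subtractive loop terminates on cyclic graphs", {
  cyc <- "ACGGTCTA"
  g <- build_graph(rep(paste0(cyc, cyc, substr(cyc, 1, 4)), 4), 5)
  contigs <- assemble_sw(g, min_coverage = 2)
  expect_gte(length(contigs), 1L)
  expect_true(all(g$cov < 2))   # loop ended because the floor is unmet
  # self-loop-ish homopolymer run
  g2 <- build_graph(rep("AAAAAAAAAA", 3), 5)
  expect_no_error(assemble_sw(g2, min_coverage = 2))
})

test_that("total coverage strictly decreases every subtractive step", {
  ts <- two_strain_small()
  g <- build_graph(ts$reads, ts$k)
  totals <- sum(g$cov[g$alive])
  repeat {
    live <- which(g$alive & g$cov >= 2)
    if (!length(live)) break
    comp <- component_scan(g, g$kmers[live[1L]], budget = 1000,
                           exclude = g$cov < 2)
    ct <- walk_max_coverage(g, comp$seed, 2)
    subtract_path_coverage(g, ct, delta_sw = 0.4)
    tot <- sum(g$cov[g$alive])
    expect_lt(tot, totals[length(totals)])
    totals <- c(totals, tot)
  }
  expect_gte(length(totals), 3L)
})
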