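test_that("graph construction matches hand enumeration", {
  g <- build_graph("AACCG", k = 3)
  nd <- graph_nodes(g)
  expect_equal(nd$kmer, c("AAC", "ACC", "CCG"))
  expect_equal(nd$coverage, c(1, 1, 1))
  # chain edges AAC -> ACC -> CCG
  nb <- straingraph:::neighbors(g, 1L, "+")
  expect_equal(nb$index, 2L)
  nb2 <- straingraph:::neighbors(g, 2L, "+")
  expect_equal(nb2$index, 3L)

  # coverage is additive over duplicate reads
  g2 <- build_graph(c("AACCG", "AACCG"), k = 3)
  expect_equal(graph_nodes(g2)$coverage, c(2, 2, 2))

  # reads shorter than k and all-N windows contribute nothing
  expect_warning(g3 <- build_graph("AANCG", k = 3), "no valid k-mers")
  expect_equal(sum(g3$alive), 0L)
  expect_warning(g4 <- build_graph("AC", k = 3), "no valid k-mers")
  expect_equal(sum(g4$alive), 0L)
})

test_that("coverage conservation: node coverages sum to valid windows", {
  set.seed(12)
  for (rep in 1:5) {
    reads <- vapply(1:4, function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), sample(6:30, 1),
                   replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
            collapse = "")
    }, character(1))
    k <- 5
    windows <- sum(vapply(reads, function(r) {
      cw <- straingraph:::canonical_windows(r, k)
      sum(cw$valid)
    }, numeric(1)))
    g <- suppressWarnings(build_graph(reads, k))
    expect_equal(sum(graph_nodes(g)$coverage), windows)
  }
})

test_that("graph is invariant under reverse-complementing the reads", {
  set.seed(3)
  reads <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  }, character(1))
  g1 <- build_graph(reads, 7)
  g2 <- build_graph(revcomp(reads), 7)
  expect_identical(graph_nodes(g1), graph_nodes(g2))
})

test_that("every edge has its mirror on the neighbor", {
  set.seed(9)
  reads <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  }, character(1))
  g <- build_graph(reads, 5)
  expect_true(isTRUE(straingraph:::check_edge_symmetry(g)))
})

test_that("node iteration order is sorted and deterministic", {
  set.seed(4)
  reads <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  }, character(1))
  g1 <- build_graph(reads, 7)
  g2 <- build_graph(reads, 7)
  expect_identical(g1$kmers, sort(g1$kmers, method = "radix"))
  expect_identical(graph_nodes(g1), graph_nodes(g2))
})

test_that("low-coverage nodes are removed before tip clipping", {
  # coverages {2,1,3}: the coverage-1 node falls to the floor of 2
  g <- build_graph(c("AACCG", "ACCGT", "ACCGT", "CCGTT", "CCGTT",
                     "CCGTT"), 5)
  nd <- graph_nodes(g)
  expect_setequal(nd$coverage, c(2, 1, 3))
  res <- prune_graph(g, max_tip_length = 0, min_coverage = 2)
  expect_equal(res$low_coverage_removed, 1L)
  expect_true(all(graph_nodes(g)$coverage >= 2))
})

test_that("a side tip off a branching chain is clipped, the chain kept", {
  main <- random_genome(40, seed = 3, distinct_k = 5)
  nat <- substr(main, 23, 23)
  tip <- paste0(substr(main, 18, 22), setdiff(BASES4, nat)[1L])
  g <- build_graph(c(rep(main, 3), tip), 5)
  n0 <- sum(g$alive)
  res <- prune_graph(g, max_tip_length = 100, min_coverage = 0)
  expect_equal(res$tips_removed, 1L)
  expect_equal(sum(g$alive), n0 - 1L)
  # idempotent: a second pass changes nothing
  res2 <- prune_graph(g, max_tip_length = 100, min_coverage = 0)
  expect_equal(res2$tips_removed, 0L)
  expect_equal(res2$low_coverage_removed, 0L)
})

test_that("dead-end chains longer than the bound are retained", {
  k <- 15
  branch <- random_genome(250, seed = 31, distinct_k = k)
  side <- random_genome(101, seed = 32, distinct_k = k)
  stopifnot(length(intersect(
    straingraph:::canonical_windows(branch, k)$canonical,
    straingraph:::canonical_windows(side, k)$canonical)) == 0)
  side_read <- paste0(substr(branch, 50, 50 + k - 1L), side)
  g <- build_graph(c(rep(branch, 2), rep(side_read, 2)), k)
  res <- prune_graph(g, max_tip_length = 100, min_coverage = 0)
  expect_equal(res$tips_removed, 0L)           # 101 nodes > bound 100
  g2 <- build_graph(c(rep(branch, 2), rep(side_read, 2)), k)
  res2 <- prune_graph(g2, max_tip_length = 101, min_coverage = 0)
  expect_equal(res2$tips_removed, 101L)        # now within the bound
})

test_that("component scan finds size and the highest-coverage seed", {
  c1 <- random_genome(40, seed = 61, distinct_k = 15)
  c2 <- random_genome(40, seed = 62, distinct_k = 15)
  g <- build_graph(c(rep(c1, 5), rep(c2, 9)), 15)
  s1 <- component_scan(g, canonical_kmer(substr(c1, 1, 15))$kmer)
  expect_equal(s1$size, 26L)
  expect_equal(unique(g$cov[match(s1$nodes, g$kmers)]), 5)
  expect_false(s1$truncated)
  # seed = highest coverage, ties by smallest k-mer
  expect_equal(s1$seed, sort(s1$nodes, method = "radix")[1L])
  # isolated scan on the other component sees coverage 9
  s2 <- component_scan(g, canonical_kmer(substr(c2, 1, 15))$kmer)
  expect_equal(s2$size, 26L)
  expect_equal(unique(g$cov[match(s2$nodes, g$kmers)]), 9)
  expect_error(component_scan(g, strrep("A", 15)), "not present")
})

test_that("budgeted component scan reports a truncated lower bound", {
  chain <- random_genome(40, seed = 51, distinct_k = 15)
  g <- build_graph(chain, 15)
  cs <- component_scan(g, g$kmers[1L], budget = 5)
  expect_equal(cs$size, 5L)
  expect_true(cs$truncated)
  full <- component_scan(g, g$kmers[1L])
  expect_equal(full$size, 26L)
  expect_false(full$truncated)
})

test_that("graphs round-trip through the binary container", {
  set.seed(8)
  reads <- vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  }, character(1))
  g <- build_graph(reads, 7)
  g$cov[2L] <- 3.25  # fractional coverage must survive
  f <- tempfile(fileext = ".sfdbg")
  save_graph(g, f)
  g2 <- load_graph(f)
  expect_identical(graph_nodes(g), graph_nodes(g2))
  expect_equal(graph_k(g2), 7L)
})

test_that("loading rejects bad magic and version", {
  f <- tempfile()
  writeBin(charToRaw("NOTAGRAPH"), f)
  expect_error(load_graph(f), "magic")
})

test_that("merging sums coverages and unions edges; k must match", {
  ga <- build_graph("AACCG", 3)      # AAC:1 ACC:1 CCG:1
  gb <- build_graph(c("AACCG", "ACCGT"), 3)
  gm <- merge_graphs(ga, gb)
  nd <- graph_nodes(gm)
  expect_equal(nd$coverage[nd$kmer == "AAC"], 2)
  expect_equal(nd$coverage[nd$kmer == "ACC"], 3)
  expect_true("ACG" %in% nd$kmer)    # canonical of CGT
  expect_true(isTRUE(straingraph:::check_edge_symmetry(gm)))
  gk <- build_graph("AACCGTT", 5)
  expect_error(merge_graphs(ga, gk), "different k")
  # split-build-merge reproduces the single-pass graph
  reads <- c("AACCGTAC", "CCGTACGG", "TTGACCAA")
  g_all <- build_graph(reads, 5)
  g_m <- merge_graphs(build_graph(reads[1:2], 5),
                      build_graph(reads[3], 5))
  expect_identical(graph_nodes(g_all), graph_nodes(g_m))
})
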