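test_that("a single candidate branch above the floor is taken", {
  g <- build_graph(c(rep("AACCGTA", 10)), 5)
  i <- match(canonical_kmer("AACCG")$kmer, g$kmers)
  ch <- choose_branch_mc(g, i, "+", min_coverage = 2)
  expect_equal(ch$base, "T")
  # below the floor: no branch
  expect_null(choose_branch_mc(g, i, "+", min_coverage = 11))
})

test_that("a collectively stronger bubble overrides the straight branch", {
  # straight 10 vs bubble arms 4 + 7: combined 11 > 10, take the 7 arm
  fx <- bubble_graph(10, 4, 7)
  ch <- choose_branch_mc(fx$graph, fx$branch_index, fx$branch_orient,
                         min_coverage = 2, lookahead = 64)
  expect_equal(ch$base, "G")
  expect_equal(ch$coverage, 7)
})

test_that("a collectively weaker bubble loses to the straight branch", {
  # straight 10 vs arms 4 + 5: combined 9 < 10, keep the straight branch
  fx <- bubble_graph(10, 4, 5)
  ch <- choose_branch_mc(fx$graph, fx$branch_index, fx$branch_orient,
                         min_coverage = 2, lookahead = 64)
  expect_equal(ch$base, "A")
  expect_equal(ch$coverage, 10)
})

test_that("consensus walk spans a linear chain from a middle seed", {
  s <- random_genome(19, seed = 71, distinct_k = 15)  # 5 nodes at k=15
  g <- build_graph(rep(s, 3), 15)
  seed <- g$kmers[3L]
  ct <- walk_consensus(g, seed, min_coverage = 2)
  expect_equal(length(ct$kmers), 5L)
  expect_equal(nchar(ct$sequence), 5L + 15L - 1L)
  expect_true(ct$sequence %in% c(s, revcomp(s)))
  expect_equal(ct$coverages, rep(3, 5))
})

test_that("a cycle is traversed once and the walk stops on revisit", {
  cyc <- "ACGGTCTA"
  g <- build_graph(paste0(cyc, cyc, substr(cyc, 1, 4)), 5)
  expect_equal(sum(g$alive), 8L)
  ct <- walk_consensus(g, component_scan(g, g$kmers[1L])$seed,
                       min_coverage = 1)
  expect_equal(length(ct$kmers), 8L)
  expect_false(anyDuplicated(ct$kmers) > 0)
})

test_that("an isolated node spells a single k-mer", {
  g <- build_graph("AACCG", 5)
  ct <- walk_consensus(g, g$kmers[1L], min_coverage = 1)
  expect_equal(length(ct$kmers), 1L)
  expect_equal(nchar(ct$sequence), 5L)
  expect_error(walk_consensus(g, g$kmers[1L], min_coverage = 5),
               "below the floor")
})

test_that("a SNP bubble becomes one alternative path with two junctions", {
  sb <- snp_bubble()
  res <- assemble_mc(copy_graph(sb$graph), min_coverage = 2)
  expect_equal(length(res$contigs), 1L)
  expect_true(res$contigs[[1L]]$sequence %in% c(sb$sA, revcomp(sb$sA)))
  doc <- res$docs[[1L]]
  expect_equal(nrow(doc$segments), 2L)   # consensus + 1 alternative
  expect_equal(nrow(doc$edges), 2L)      # entry + exit junction
  expect_equal(sort(names(doc$paths)), c("alt_1", "consensus"))
})

test_that("paths without qualifying off-path branches yield a bare doc", {
  s <- random_genome(60, seed = 81, distinct_k = 15)
  g <- build_graph(rep(s, 3), 15)
  ct <- walk_consensus(g, component_scan(g, g$kmers[1L])$seed, 2)
  doc <- explore_local_variants(g, ct, min_coverage = 2)
  expect_equal(nrow(doc$segments), 1L)
  expect_equal(nrow(doc$edges), 0L)
})

test_that("off-path branches that dead-end produce no alternative", {
  main <- random_genome(60, seed = 3, distinct_k = 15)
  side <- random_genome(20, seed = 4, distinct_k = 15)
  stopifnot(length(intersect(
    straingraph:::canonical_windows(main, 15)$canonical,
    straingraph:::canonical_windows(side, 15)$canonical)) == 0)
  dead <- paste0(substr(main, 20, 34), side)  # spur that never rejoins
  g <- build_graph(c(rep(main, 5), rep(dead, 3)), 15)
  ct <- walk_consensus(g, component_scan(g, g$kmers[1L])$seed, 2)
  expect_true(ct$sequence %in% c(main, revcomp(main)))
  doc <- explore_local_variants(g, ct, min_coverage = 2)
  expect_equal(nrow(doc$segments), 1L)
})

test_that("one contig per connected component in default mode", {
  c1 <- random_genome(60, seed = 91, distinct_k = 15)
  c2 <- random_genome(60, seed = 92, distinct_k = 15)
  g <- build_graph(c(rep(c1, 4), rep(c2, 4)), 15)
  res <- assemble_mc(g, min_coverage = 2, explore_variants = FALSE)
  expect_equal(length(res$contigs), 2L)
  seqs <- vapply(res$contigs, `[[`, character(1), "sequence")
  expect_setequal(
    vapply(seqs, function(s) min(s, revcomp(s)), character(1),
           USE.NAMES = FALSE),
    vapply(c(c1, c2), function(s) min(s, revcomp(s)), character(1),
           USE.NAMES = FALSE))
})

test_that("all nodes below the floor assemble to nothing", {
  s <- random_genome(12, seed = 110, distinct_k = 5)
  g <- build_graph(s, 5)  # every node coverage 1
  expect_true(all(graph_nodes(g)$coverage == 1))
  res <- assemble_mc(g, min_coverage = 2, explore_variants = FALSE)
  expect_equal(length(res$contigs), 0L)
})

test_that("-M mode yields multiple node-disjoint contigs per component", {
  k <- 15
  M <- random_genome(80, seed = 41, distinct_k = k)
  A1 <- random_genome(60, seed = 42, distinct_k = k)
  A2 <- random_genome(60, seed = 43, distinct_k = k)
  B1 <- random_genome(60, seed = 44, distinct_k = k)
  B2 <- random_genome(60, seed = 45, distinct_k = k)
  reads <- c(rep(paste0(A1, M, A2), 10), rep(paste0(B1, M, B2), 4))
  res1 <- assemble_mc(build_graph(reads, k), 2, multiple_contigs = FALSE,
                      explore_variants = FALSE)
  expect_equal(length(res1$contigs), 1L)
  res2 <- assemble_mc(build_graph(reads, k), 2, multiple_contigs = TRUE,
                      explore_variants = FALSE)
  expect_gte(length(res2$contigs), 2L)
  kk <- unlist(lapply(res2$contigs, `[[`, "kmers"))
  expect_false(anyDuplicated(kk) > 0)
})

test_that("default mode consumes every scanned node exactly once", {
  ts <- two_strain_small()
  g <- build_graph(ts$reads, ts$k)
  res <- assemble_mc(g, min_coverage = 2, explore_variants = FALSE)
  # the shared-core component yields one contig; nodes of all contigs are
  # unique and every graph node was scanned (consumed)
  kk <- unlist(lapply(res$contigs, `[[`, "kmers"))
  expect_false(anyDuplicated(kk) > 0)
})

test_that("consensus walk matches the independent greedy oracle", {
  checked <- 0L
  seed <- 0L
  while (checked < 60L && seed < 4000L) {
    seed <- seed + 1L
    g <- random_small_graph(seed)
    if (is.null(g)) next
    nd <- graph_nodes(g)
    if (has_candidate_bubble(nd, 7, min_cov = 1)) next
    oracle <- oracle_greedy_path(nd, 7, min_cov = 1)
    ct <- walk_consensus(g, oracle$seed, min_coverage = 1)
    expect_equal(ct$kmers, oracle$kmers,
                 info = sprintf("graph seed %d", seed))
    checked <- checked + 1L
  }
  expect_gte(checked, 60L)
})

test_that("unitigs are node-disjoint, covering, with degree-2 interiors", {
  sb <- snp_bubble()
  g <- copy_graph(sb$graph)
  ut <- assemble_unitigs(g, min_coverage = 2)
  kk <- unlist(lapply(ut, `[[`, "kmers"))
  expect_false(anyDuplicated(kk) > 0)
  expect_equal(sort(kk), sort(g$kmers[g$alive & g$cov >= 2]))
  # interior nodes have exactly one edge each way within the subgraph
  skip_mask <- !(g$alive & g$cov >= 2)
  for (ct in ut) {
    idx <- match(ct$kmers, g$kmers)
    if (length(idx) < 3L) next
    for (p in 2:(length(idx) - 1L)) {
      expect_equal(straingraph:::node_degree(g, idx[p], "+",
                                             exclude = skip_mask), 1L)
      expect_equal(straingraph:::node_degree(g, idx[p], "-",
                                             exclude = skip_mask), 1L)
    }
  }
})
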