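# Shared fixtures, memoized so expensive builds run once per test session.
.fx <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, expr, envir = .fx)
  get(name, envir = .fx)
}

BASES4 <- c("A", "C", "G", "T")

# -- bubble-rule junction ------------------------------------------------
# Frozen k=5 literals: shared prefix P, two bubble arms rejoining in Z, and
# a straight arm. Arm-specific k-mers verified disjoint at build time.
bubble_seqs <- list(
  P = "ACGTAGGT",
  Z = "TTACGCAT",
  straight = "ACGTAGGTAGCCTAT",
  arm1 = "ACGTAGGTCGCCACTTACGCAT",
  arm2 = "ACGTAGGTGTTCGATTACGCAT"
)

bubble_graph <- function(n_straight, n_arm1, n_arm2, k = 5) {
  s <- bubble_seqs
  canon <- function(x) {
    cw <- straingraph:::canonical_windows(x, k)
    cw$canonical
  }
  shared <- c(canon(s$P), canon(s$Z))
  u0 <- setdiff(canon(s$straight), shared)
  u1 <- setdiff(canon(s$arm1), shared)
  u2 <- setdiff(canon(s$arm2), shared)
  stopifnot(length(intersect(u0, c(u1, u2))) == 0,
            length(intersect(u1, u2)) == 0)
  g <- build_graph(c(rep(s$straight, n_straight), rep(s$arm1, n_arm1),
                     rep(s$arm2, n_arm2)), k)
  br <- canonical_kmer(substr(s$P, nchar(s$P) - k + 1L, nchar(s$P)))
  list(graph = g,
       branch_index = match(br$kmer, g$kmers),
       branch_orient = if (br$orientation == "forward") "+" else "-")
}

# -- SNP bubble between two strains --------------------------------------
snp_bubble <- function() {
  fixture("snp_bubble", {
    k <- 15
    sA <- random_genome(200, seed = 5, distinct_k = k)
    pos <- 100L
    b <- strsplit(sA, "")[[1L]]
    alt <- setdiff(BASES4, b[pos])[1L]
    sB <- paste0(substr(sA, 1L, pos - 1L), alt,
                 substr(sA, pos + 1L, nchar(sA)))
    g <- build_graph(c(rep(sA, 10), rep(sB, 4)), k)
    list(k = k, sA = sA, sB = sB, snp_pos = pos, graph = g)
  })
}

# -- two strains sharing a core (small, for SW unit tests) ---------------
two_strain_small <- function() {
  fixture("two_strain_small", {
    k <- 15
    core <- random_genome(120, seed = 21, distinct_k = k)
    fA1 <- random_genome(60, seed = 22, distinct_k = k)
    fA2 <- random_genome(60, seed = 23, distinct_k = k)
    fB1 <- random_genome(60, seed = 24, distinct_k = k)
    fB2 <- random_genome(60, seed = 25, distinct_k = k)
    sA <- paste0(fA1, core, fA2)
    sB <- paste0(fB1, core, fB2)
    list(k = k, core = core, sA = sA, sB = sB,
         reads = c(rep(sA, 10), rep(sB, 10)))
  })
}

# -- 2 kb genome with full-tiling 30x reads (perfect reconstruction) -----
perfect2kb <- function() {
  fixture("perfect2kb", {
    gen <- random_genome(2000, seed = 42, distinct_k = 31)
    comm <- simulated_community(c(g1 = gen), read_length = 150,
                                depth = 30, layout = "tiling", seed = 7)
    list(genome = gen, reads = simulate_reads(comm))
  })
}

# -- two 2.5 kb strains, 1 kb shared core, 500 bp flanks, 50x ------------
two_strain_50x <- function() {
  fixture("two_strain_50x", {
    k <- 31
    core <- random_genome(1000, seed = 11, distinct_k = k)
    fA1 <- random_genome(500, seed = 12, distinct_k = k)
    fA2 <- random_genome(500, seed = 13, distinct_k = k)
    fB1 <- random_genome(500, seed = 14, distinct_k = k)
    fB2 <- random_genome(500, seed = 15, distinct_k = k)
    sA <- paste0(fA1, core, fA2)
    sB <- paste0(fB1, core, fB2)
    comm <- simulated_community(c(A = sA, B = sB), read_length = 150,
                                depth = 50, layout = "tiling", seed = 8)
    list(k = k, sA = sA, sB = sB, core = core,
         reads = simulate_reads(comm))
  })
}

# -- independent greedy-walk oracle --------------------------------------
# Works only from graph_nodes() output (k-mer, coverage, and the two
# documented edge masks with bits A=1, C=2, G=4, T=8); its own reverse
# complement, mask decoding, neighbor spelling, and walk loop.
rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

oracle_table <- function(node_df) {
  tab <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(node_df))) {
    assign(node_df$kmer[i],
           list(cv = node_df$coverage[i], mf = node_df$edges_fwd[i],
                mr = node_df$edges_rev[i]),
           envir = tab)
  }
  tab
}

# Outgoing bases recorded for the oriented text `text` (canonical or its
# reverse complement) according to the stored edge masks.
oracle_out_bases <- function(tab, text) {
  rct <- rc_chr(text)
  canon <- if (text <= rct) text else rct
  node <- tab[[canon]]
  if (is.null(node)) return(character(0))
  mask <- if (text == canon) node$mf else node$mr
  BASES4[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
}

oracle_best_branch <- function(tab, k, text, min_cov) {
  best <- NULL
  for (b in oracle_out_bases(tab, text)) {
    nt <- paste0(substr(text, 2L, k), b)
    rcnt <- rc_chr(nt)
    canon <- if (nt <= rcnt) nt else rcnt
    node <- tab[[canon]]
    if (is.null(node) || node$cv < min_cov) next
    if (is.null(best) || node$cv > best$cv) {
      best <- list(text = nt, canon = canon, cv = node$cv)
    }
  }
  best
}

oracle_greedy_path <- function(node_df, k, min_cov = 1) {
  tab <- oracle_table(node_df)
  ord <- order(-node_df$coverage, node_df$kmer, method = "radix")
  seed <- node_df$kmer[ord[1L]]
  walk <- function(text, used) {
    out <- character(0)
    repeat {
      s <- oracle_best_branch(tab, k, text, min_cov)
      if (is.null(s) || s$canon %in% used) break
      out <- c(out, s$canon)
      used <- c(used, s$canon)
      text <- s$text
    }
    out
  }
  fwd <- walk(seed, seed)
  bwd <- walk(rc_chr(seed), c(seed, fwd))
  list(seed = seed, kmers = c(rev(bwd), seed, fwd))
}

# Bounded greedy walk from one branch for the bubble filter (node k-mers
# visited, cycle-safe within the walk).
oracle_branch_walk <- function(tab, k, text, min_cov, bound = 64L) {
  out <- character(0)
  repeat {
    if (length(out) >= bound) break
    s <- oracle_best_branch(tab, k, text, min_cov)
    if (is.null(s) || s$canon %in% out) break
    out <- c(out, s$canon)
    text <- s$text
  }
  out
}

# TRUE when some fork in the graph has two branches whose greedy walks
# share a node (a candidate bubble for the consensus rule).
has_candidate_bubble <- function(node_df, k, min_cov = 1) {
  tab <- oracle_table(node_df)
  for (km in node_df$kmer) {
    for (text in unique(c(km, rc_chr(km)))) {
      branches <- character(0)
      for (b in oracle_out_bases(tab, text)) {
        nt <- paste0(substr(text, 2L, k), b)
        rcnt <- rc_chr(nt)
        canon <- if (nt <= rcnt) nt else rcnt
        node <- tab[[canon]]
        if (is.null(node) || node$cv < min_cov) next
        branches <- c(branches, nt)
      }
      if (length(branches) < 2L) next
      walks <- lapply(branches, function(bt) {
        rcbt <- rc_chr(bt)
        c(if (bt <= rcbt) bt else rcbt,
          oracle_branch_walk(tab, k, bt, min_cov))
      })
      for (a in seq_len(length(walks) - 1L)) {
        for (b2 in (a + 1L):length(walks)) {
          if (length(intersect(walks[[a]], walks[[b2]]))) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Random small graphs for the oracle property: a few short reads at k=7.
random_small_graph <- function(seed, k = 7, max_nodes = 12) {
  set.seed(seed)
  n_reads <- sample(1:3, 1)
  reads <- vapply(seq_len(n_reads), function(i) {
    paste(sample(BASES4, sample(10:18, 1), replace = TRUE), collapse = "")
  }, character(1))
  reads <- rep(reads, times = sample(1:5, n_reads, replace = TRUE))
  g <- suppressWarnings(build_graph(reads, k))
  if (sum(g$alive) == 0 || sum(g$alive) > max_nodes) return(NULL)
  g
}
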