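## Canonical-k-mer de Bruijn graph.
##
## Nodes are canonical k-mers. Each node stores a coverage count and two
## 4-bit edge masks: one for the outgoing edges read in the canonical
## ("forward") orientation, one for the reverse-complement orientation.
## Bits follow base order A=1, C=2, G=4, T=8. The graph is an environment,
## so coverage mutation (subtractive walk) and node removal (pruning) have
## reference semantics, like the field's hash-table assemblers.

BASES <- c("A", "C", "G", "T")
BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

base_bit <- function(b) BASE_BITS[b]

new_dbg <- function(k, kmers, cov, ef, er) {
  g <- new.env(parent = emptyenv())
  g$k <- as.integer(k)
  ord <- order_c(kmers)
  g$kmers <- kmers[ord]
  g$rc <- revcomp(g$kmers)
  g$cov <- as.numeric(cov[ord])
  g$ef <- as.integer(ef[ord])
  g$er <- as.integer(er[ord])
  g$alive <- rep(TRUE, length(kmers))
  g$index <- build_index(g$kmers)
  class(g) <- "dbg_graph"
  g
}

build_index <- function(kmers) {
  idx <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(29L, length(kmers)))
  for (i in seq_along(kmers)) assign(kmers[i], i, envir = idx)
  idx
}

node_index <- function(graph, kmer) {
  i <- graph$index[[kmer]]
  if (is.null(i)) NA_integer_ else i
}

#' Build a de Bruijn graph from reads
#'
#' Every k-length window free of `N` contributes one coverage unit to its
#' canonical k-mer node; consecutive windows of a read induce the
#' corresponding oriented edge on both endpoints. Reads shorter than k
#' contribute nothing. Because storage is canonical, the graph is invariant
#' under reverse-complementing any read.
#'
#' @param reads Character vector of read sequences, or a data frame with a
#'   `sequence` column as returned by [read_sequences()].
#' @param k Odd k-mer length between 3 and 191.
#' @return A `dbg_graph` object (an environment; modified by reference by
#'   [prune_graph()], [subtract_path_coverage()] and the assemblers).
#' @examples
#' g <- build_graph(c("AACCG", "AACCG"), k = 3)
#' graph_nodes(g)
#' @export
build_graph <- function(reads, k) {
  k <- check_k(k)
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- toupper(as.character(reads))
  reads <- reads[nchar(reads) >= k]

  rc_reads <- revcomp(reads)
  cov_parts <- vector("list", length(reads))
  e_kmer <- vector("list", length(reads))
  e_side <- vector("list", length(reads))
  e_bit <- vector("list", length(reads))
  for (r in seq_along(reads)) {
    cw <- canonical_windows(reads[r], k, rc_reads[r])
    m <- length(cw$window)
    cov_parts[[r]] <- cw$canonical[cw$valid]
    if (m >= 2L) {
      i <- which(cw$valid[-m] & cw$valid[-1L])
      if (length(i)) {
        out_base <- substring(reads[r], i + k, i + k)
        in_base <- substring(reads[r], i, i)
        e_kmer[[r]] <- c(cw$canonical[i], cw$canonical[i + 1L])
        e_side[[r]] <- c(ifelse(cw$forward[i], "f", "r"),
                         ifelse(cw$forward[i + 1L], "r", "f"))
        e_bit[[r]] <- c(base_bit(out_base), base_bit(comp_base(in_base)))
      }
    }
  }

  covered <- unlist(cov_parts, use.names = FALSE)
  if (!length(covered)) {
    warning("no valid k-mers in input; returning an empty graph")
    return(new_dbg(k, character(0), numeric(0), integer(0), integer(0)))
  }
  cov_dt <- data.table::data.table(kmer = covered)
  cov_dt <- cov_dt[, list(cov = .N), by = "kmer"]

  edges <- data.table::data.table(
    kmer = unlist(e_kmer, use.names = FALSE),
    side = unlist(e_side, use.names = FALSE),
    bit = unlist(e_bit, use.names = FALSE))
  if (nrow(edges)) {
    edges <- unique(edges)
    edges <- edges[, list(mask = Reduce(bitwOr, bit)), by = c("kmer", "side")]
    ef <- edges[edges$side == "f", ]
    er <- edges[edges$side == "r", ]
  } else {
    ef <- er <- data.table::data.table(kmer = character(0), mask = integer(0))
  }
  mf <- ef$mask[match(cov_dt$kmer, ef$kmer)]
  mr <- er$mask[match(cov_dt$kmer, er$kmer)]
  mf[is.na(mf)] <- 0L
  mr[is.na(mr)] <- 0L
  new_dbg(k, cov_dt$kmer, cov_dt$cov, mf, mr)
}

#' @export
print.dbg_graph <- function(x, ...) {
  cat("de Bruijn graph: k =", x$k, "|", sum(x$alive), "nodes",
      sprintf("(total coverage %.1f)\n", sum(x$cov[x$alive])))
  invisible(x)
}

#' Graph node table
#'
#' @param graph A `dbg_graph`.
#' @param alive_only Drop removed (pruned/consumed) nodes; default `TRUE`.
#' @return A data frame with `kmer`, `coverage` and the two 4-bit edge
#'   masks (`edges_fwd`, `edges_rev`; bits A=1, C=2, G=4, T=8), sorted by
#'   canonical k-mer.
#' @export
graph_nodes <- function(graph, alive_only = TRUE) {
  keep <- if (alive_only) graph$alive else rep(TRUE, length(graph$kmers))
  data.frame(kmer = graph$kmers[keep],
             coverage = graph$cov[keep],
             edges_fwd = graph$ef[keep],
             edges_rev = graph$er[keep],
             stringsAsFactors = FALSE)
}

#' @rdname graph_nodes
#' @export
graph_k <- function(graph) graph$k

#' Coverage of one node
#' @param graph A `dbg_graph`.
#' @param kmer Canonical k-mer text.
#' @return Numeric coverage (may be fractional after subtraction).
#' @export
node_coverage <- function(graph, kmer) {
  i <- node_index(graph, kmer)
  if (is.na(i) || !graph$alive[i]) stop("no such node: ", kmer)
  graph$cov[i]
}

#' Deep copy of a graph
#'
#' `dbg_graph` objects are environments, so the assemblers that mutate
#' coverage act on the caller's object; use `copy_graph()` to keep the
#' original.
#' @param graph A `dbg_graph`.
#' @return An independent copy.
#' @export
copy_graph <- function(graph) {
  g <- new.env(parent = emptyenv())
  for (f in c("k", "kmers", "rc", "cov", "ef", "er", "alive")) {
    assign(f, get(f, envir = graph), envir = g)
  }
  g$index <- graph$index  # index is immutable (positions never change)
  class(g) <- "dbg_graph"
  g
}

# Oriented text of node i: the canonical k-mer for "+", its reverse
# complement for "-".
oriented_text <- function(graph, i, orient) {
  if (orient == "+") graph$kmers[i] else graph$rc[i]
}

flip_orient <- function(orient) ifelse(orient == "+", "-", "+")

# Out-neighbours of (node i, orientation). Returns a data frame with one
# row per edge: base, index, orient of the neighbour as entered, and its
# coverage. Removed nodes (alive = FALSE) and optionally `exclude`d nodes
# are filtered out, as are edges whose target is absent from the graph
# (dangling after pruning).
neighbors <- function(graph, i, orient, exclude = NULL) {
  mask <- if (orient == "+") graph$ef[i] else graph$er[i]
  if (mask == 0L) {
    return(data.frame(base = character(0), index = integer(0),
                      orient = character(0), coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  k <- graph$k
  txt <- oriented_text(graph, i, orient)
  rc_txt <- oriented_text(graph, i, flip_orient(orient))
  suffix <- substr(txt, 2L, k)
  rc_prefix <- substr(rc_txt, 1L, k - 1L)
  bases <- BASES[bitwAnd(mask, BASE_BITS) > 0L]
  out <- lapply(bases, function(b) {
    nxt <- paste0(suffix, b)
    rc_nxt <- paste0(comp_base(b), rc_prefix)
    if (nxt <= rc_nxt) {
      canon <- nxt; o2 <- "+"
    } else {
      canon <- rc_nxt; o2 <- "-"
    }
    j <- node_index(graph, canon)
    if (is.na(j) || !graph$alive[j]) return(NULL)
    if (!is.null(exclude) && exclude[j]) return(NULL)
    data.frame(base = b, index = j, orient = o2, coverage = graph$cov[j],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(base = character(0), index = integer(0),
                      orient = character(0), coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Degree of (node, orientation) under the alive/exclude filters.
node_degree <- function(graph, i, orient, exclude = NULL) {
  nrow(neighbors(graph, i, orient, exclude))
}

#' Prune tips and low-coverage nodes
#'
#' Error clean-up in two passes. First every node below the coverage floor
#' is removed. Then tips are clipped: at every fork (a node with two or
#' more outgoing edges on one side), each branch is chased; a branch that
#' runs as a simple chain into a dead end within `max_tip_length` nodes is
#' a clippable tip. If the fork has any non-tip branch (one that continues
#' past the bound or into further structure), all tips at that fork are
#' clipped; if every branch is a tip -- as at the end of a linear genome
#' with a side artefact -- the best one is kept (highest mean coverage,
#' ties broken by length, then by first k-mer) and the rest are clipped.
#' Clipping iterates to a fixed point, since removing one tip can expose
#' another. A free-standing chain with no fork is never touched. Defaults
#' follow the assembler's convention: minimum coverage 2, tips up to 100
#' nodes.
#'
#' @param graph A `dbg_graph`; modified in place.
#' @param max_tip_length Maximum tip length in nodes (0 disables clipping).
#' @param min_coverage Coverage floor; nodes with coverage strictly below
#'   are removed (0 disables).
#' @return Invisibly, a list with `tips_removed` and `low_coverage_removed`
#'   node counts.
#' @export
prune_graph <- function(graph, max_tip_length = 100L, min_coverage = 2) {
  stopifnot(max_tip_length >= 0, min_coverage >= 0)
  low <- graph$alive & graph$cov < min_coverage
  graph$alive[low] <- FALSE
  n_low <- sum(low)

  n_tip <- 0L
  if (max_tip_length > 0L) {
    repeat {
      removed <- 0L
      for (i in which(graph$alive)) {
        if (!graph$alive[i]) next  # may have been clipped this sweep
        for (o in c("+", "-")) {
          nb <- neighbors(graph, i, o)
          if (nrow(nb) < 2L) next
          chains <- lapply(seq_len(nrow(nb)), function(r) {
            chase_tip(graph, nb$index[r], nb$orient[r], max_tip_length)
          })
          clippable <- !vapply(chains, is.null, logical(1))
          if (!any(clippable)) next
          drop <- if (all(clippable)) {
            covs <- vapply(chains, function(ch) mean(graph$cov[ch]),
                           numeric(1))
            lens <- lengths(chains)
            first <- graph$kmers[nb$index]
            keep <- order(-covs, -lens, first, method = "radix")[1L]
            setdiff(which(clippable), keep)
          } else {
            which(clippable)
          }
          for (r in drop) {
            graph$alive[chains[[r]]] <- FALSE
            removed <- removed + length(chains[[r]])
          }
        }
      }
      n_tip <- n_tip + removed
      if (removed == 0L) break
    }
  }
  invisible(list(tips_removed = n_tip, low_coverage_removed = n_low))
}

# Chase a fork branch: follow the simple chain starting at (idx, orient).
# Returns the chain's node indices if it is a clippable tip -- a chain
# whose nodes each have in-degree 1 and out-degree <= 1, ending at a dead
# end within max_len nodes -- or NULL if it merges, branches onward,
# cycles, or exceeds the bound.
chase_tip <- function(graph, idx, orient, max_len) {
  chain <- integer(0)
  cur <- idx
  o <- orient
  repeat {
    if (length(chain) >= max_len) return(NULL)
    if (node_degree(graph, cur, flip_orient(o)) != 1L) return(NULL)
    if (cur %in% chain) return(NULL)  # cycle
    chain <- c(chain, cur)
    nb <- neighbors(graph, cur, o)
    if (nrow(nb) == 0L) return(chain)   # dead end: clippable
    if (nrow(nb) >= 2L) return(NULL)    # further structure
    cur <- nb$index[1L]
    o <- nb$orient[1L]
  }
}

#' Explore a connected component
#'
#' Breadth-first search over undirected adjacency starting from one node,
#' reporting component size and the seed node for traversal: the
#' highest-coverage node found, ties broken by lexicographically smallest
#' k-mer. With a finite `budget` the search stops after that many nodes and
#' the reported size is a lower bound (`truncated = TRUE`), which speeds up
#' seed-finding in very large components.
#'
#' @param graph A `dbg_graph`.
#' @param start Canonical k-mer of the start node.
#' @param budget Maximum nodes to visit (`Inf` = exhaustive).
#' @param exclude Optional logical vector marking nodes to treat as absent.
#' @return List with `nodes` (canonical k-mers, discovery order), `size`,
#'   `seed` (k-mer), and `truncated`.
#' @export
component_scan <- function(graph, start, budget = Inf, exclude = NULL) {
  s <- node_index(graph, start)
  if (is.na(s) || !graph$alive[s] || (!is.null(exclude) && exclude[s])) {
    stop("start node not present in graph: ", start)
  }
  seen <- integer(0)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  queue <- s
  assign(as.character(s), TRUE, envir = visited)
  truncated <- FALSE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    seen <- c(seen, cur)
    nb <- rbind(neighbors(graph, cur, "+", exclude),
                neighbors(graph, cur, "-", exclude))
    fresh <- unique(nb$index)
    fresh <- fresh[vapply(as.character(fresh),
                          function(key) is.null(visited[[key]]),
                          logical(1))]
    if (length(seen) >= budget) {
      truncated <- length(queue) > 0L || length(fresh) > 0L
      break
    }
    for (j in fresh) {
      assign(as.character(j), TRUE, envir = visited)
      queue <- c(queue, j)
    }
  }
  covs <- graph$cov[seen]
  kms <- graph$kmers[seen]
  best <- which(covs == max(covs))
  seed <- kms[best][order_c(kms[best])][1L]
  list(nodes = kms, size = length(seen), seed = seed, truncated = truncated)
}

## ---- serialization ----------------------------------------------------

GRAPH_MAGIC <- "SFDBG"
GRAPH_VERSION <- 1L

#' Save and load de Bruijn graphs
#'
#' A versioned binary container: the magic string `SFDBG`, a format version
#' byte, k, the node count, then the node table (k-mer text, double
#' coverage, two edge-mask bytes per node). Only live nodes are written.
#' `merge_graphs` sums coverages of shared nodes and unions edge sets;
#' the inputs must share k. Splitting read files, building one graph per
#' chunk, saving, and merging reproduces the single-pass graph.
#'
#' @param graph A `dbg_graph`.
#' @param path File path.
#' @return `load_graph` returns a `dbg_graph`; `save_graph` returns the
#'   path invisibly.
#' @export
save_graph <- function(graph, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  keep <- graph$alive
  writeBin(charToRaw(GRAPH_MAGIC), con)
  writeBin(as.raw(GRAPH_VERSION), con)
  writeBin(graph$k, con, size = 4L, endian = "little")
  n <- sum(keep)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  if (n > 0L) {
    writeBin(charToRaw(paste(graph$kmers[keep], collapse = "")), con)
    writeBin(graph$cov[keep], con, size = 8L, endian = "little")
    writeBin(as.raw(graph$ef[keep]), con)
    writeBin(as.raw(graph$er[keep]), con)
  }
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(GRAPH_MAGIC)))
  if (!identical(magic, GRAPH_MAGIC)) {
    stop("not a graph file (bad magic): ", path)
  }
  version <- as.integer(readBin(con, "raw", 1L))
  if (version != GRAPH_VERSION) {
    stop("unsupported graph format version ", version, " in ", path)
  }
  k <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (n == 0L) {
    return(new_dbg(k, character(0), numeric(0), integer(0), integer(0)))
  }
  blob <- rawToChar(readBin(con, "raw", n * k))
  kmers <- substring(blob, (0:(n - 1L)) * k + 1L, (1:n) * k)
  cov <- readBin(con, "double", n, size = 8L, endian = "little")
  ef <- as.integer(readBin(con, "raw", n))
  er <- as.integer(readBin(con, "raw", n))
  new_dbg(k, kmers, cov, ef, er)
}

#' @rdname save_graph
#' @param a,b Graphs with equal k.
#' @export
merge_graphs <- function(a, b) {
  if (a$k != b$k) stop("cannot merge graphs with different k (",
                       a$k, " vs ", b$k, ")")
  ka <- a$kmers[a$alive]; kb <- b$kmers[b$alive]
  all_k <- sort_c(unique(c(ka, kb)))
  ia <- match(all_k, ka); ib <- match(all_k, kb)
  pos_a <- which(a$alive)[ia]; pos_b <- which(b$alive)[ib]
  cov <- ifelse(is.na(pos_a), 0, a$cov[pos_a]) +
         ifelse(is.na(pos_b), 0, b$cov[pos_b])
  ef <- bitwOr(ifelse(is.na(pos_a), 0L, a$ef[pos_a]),
               ifelse(is.na(pos_b), 0L, b$ef[pos_b]))
  er <- bitwOr(ifelse(is.na(pos_a), 0L, a$er[pos_a]),
               ifelse(is.na(pos_b), 0L, b$er[pos_b]))
  new_dbg(a$k, all_k, cov, ef, er)
}

# Graph-wide edge symmetry check (test support): every outgoing edge of a
# live node must be mirrored on its (live) target. Returns TRUE or a
# character description of the first violation.
check_edge_symmetry <- function(graph) {
  for (i in which(graph$alive)) {
    for (o in c("+", "-")) {
      nb <- neighbors(graph, i, o)
      if (!nrow(nb)) next
      back_base <- comp_base(substr(oriented_text(graph, i, o), 1L, 1L))
      for (r in seq_len(nrow(nb))) {
        mask <- if (nb$orient[r] == "+") graph$er[nb$index[r]]
                else graph$ef[nb$index[r]]
        if (bitwAnd(mask, base_bit(back_base)) == 0L) {
          return(sprintf("edge %s(%s) -%s-> %s lacks its mirror",
                         graph$kmers[i], o, nb$base[r],
                         graph$kmers[nb$index[r]]))
        }
      }
    }
  }
  TRUE
}
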