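## Consensus traversal: coverage-guided branch choice with a
## collective-coverage bubble rule, per-component contigs, and local
## variant exploration emitted as sequence graphs.

# Greedy highest-coverage lookahead walk used for bubble detection: from a
# branch target, repeatedly take the highest-coverage qualifying neighbour
# (ties in base order A<C<G<T), at most `lookahead` nodes, never revisiting
# a node within this walk. Returns indices and coverages in walk order.
lookahead_walk <- function(graph, start_idx, start_orient, min_coverage,
                           lookahead, exclude = NULL) {
  idx <- start_idx
  ori <- start_orient
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(as.character(start_idx), TRUE, envir = seen)
  while (length(idx) < lookahead) {
    nb <- neighbors(graph, idx[length(idx)], ori[length(ori)], exclude)
    nb <- nb[nb$coverage >= min_coverage, , drop = FALSE]
    nb <- nb[is.na(mget(as.character(nb$index), envir = seen,
                        ifnotfound = NA)), , drop = FALSE]
    if (!nrow(nb)) break
    best <- which(nb$coverage == max(nb$coverage))[1L]  # rows in base order
    idx <- c(idx, nb$index[best])
    ori <- c(ori, nb$orient[best])
    assign(as.character(nb$index[best]), TRUE, envir = seen)
  }
  list(index = idx, orient = ori, coverage = graph$cov[idx])
}

#' Consensus branch choice with the collective-coverage bubble rule
#'
#' At a branching point the branch whose target node has the highest
#' coverage is favoured, provided it meets the coverage floor. But if two
#' of the branches rejoin within the lookahead horizon (a bubble -- the
#' signature of a SNP or small indel between variants) and together carry
#' more coverage than any other single branch, the traversal routes through
#' the bubble: the higher-coverage member of that pair is chosen. Branch
#' coverage for the pair test is the mean node coverage along each branch's
#' greedy lookahead walk up to the rejoin point.
#'
#' @param graph A `dbg_graph`.
#' @param index Node index of the current position.
#' @param orient `"+"` or `"-"`: orientation of the current position.
#' @param min_coverage Candidate branches must reach this coverage.
#' @param lookahead Bubble-detection horizon in nodes.
#' @param exclude Optional logical vector of nodes to treat as absent.
#' @return A one-row data frame (base, index, orient, coverage) for the
#'   chosen branch, or `NULL` when no branch qualifies.
#' @export
choose_branch_mc <- function(graph, index, orient, min_coverage = 2,
                             lookahead = 64L, exclude = NULL) {
  nb <- neighbors(graph, index, orient, exclude)
  nb <- nb[nb$coverage >= min_coverage, , drop = FALSE]
  if (!nrow(nb)) return(NULL)
  if (nrow(nb) >= 2L && lookahead > 1L) {
    walks <- lapply(seq_len(nrow(nb)), function(r) {
      lookahead_walk(graph, nb$index[r], nb$orient[r], min_coverage,
                     lookahead, exclude)
    })
    branch_mean <- function(r, upto = NULL) {
      cv <- walks[[r]]$coverage
      if (!is.null(upto) && upto > 1L) cv <- cv[seq_len(upto - 1L)]
      mean(cv)
    }
    full_mean <- vapply(seq_len(nrow(nb)), branch_mean, numeric(1))
    best_pair <- NULL
    best_combined <- -Inf
    for (a in seq_len(nrow(nb) - 1L)) {
      for (b in (a + 1L):nrow(nb)) {
        pos <- match(walks[[a]]$index, walks[[b]]$index)
        hit <- which(!is.na(pos))
        if (!length(hit)) next  # no rejoin: not a bubble
        ia <- hit[1L]; ib <- pos[ia]
        ma <- branch_mean(a, ia)
        mb <- branch_mean(b, ib)
        combined <- ma + mb
        if (combined > best_combined) {
          best_combined <- combined
          best_pair <- list(a = a, b = b, ma = ma, mb = mb)
        }
      }
    }
    if (!is.null(best_pair)) {
      others <- setdiff(seq_len(nrow(nb)), c(best_pair$a, best_pair$b))
      if (all(best_combined > full_mean[others])) {
        pick <- if (best_pair$ma >= best_pair$mb) best_pair$a else
          best_pair$b
        return(nb[pick, , drop = FALSE])
      }
    }
  }
  nb[which(nb$coverage == max(nb$coverage))[1L], , drop = FALSE]
}

# Branch choice used by the subtractive walk: plain highest target
# coverage, bubbles disregarded.
choose_branch_greedy <- function(graph, index, orient, min_coverage = 2,
                                 exclude = NULL, ...) {
  nb <- neighbors(graph, index, orient, exclude)
  nb <- nb[nb$coverage >= min_coverage, , drop = FALSE]
  if (!nrow(nb)) return(NULL)
  nb[which(nb$coverage == max(nb$coverage))[1L], , drop = FALSE]
}

# Shared bidirectional walk engine. Extends forward from the seed, then
# extends from the seed in the reverse orientation and prepends the
# reverse-complemented steps, so the result is reported 5'->3' on the
# spelled strand. Terminates on: no qualifying branch (dead end or
# coverage floor), or the chosen branch leading to a node already in this
# path (repeats, cycles).
walk_engine <- function(graph, seed, min_coverage, chooser, exclude = NULL) {
  s <- node_index(graph, seed)
  if (is.na(s) || !graph$alive[s]) stop("seed node not in graph: ", seed)
  if (graph$cov[s] < min_coverage) {
    stop("seed coverage ", graph$cov[s], " is below the floor ",
         min_coverage)
  }
  in_path <- new.env(hash = TRUE, parent = emptyenv())
  assign(as.character(s), TRUE, envir = in_path)

  extend <- function(start_orient) {
    idx <- integer(0); ori <- character(0)
    cur <- s; cur_o <- start_orient
    repeat {
      ch <- chooser(graph, cur, cur_o, min_coverage, exclude = exclude)
      if (is.null(ch)) break
      if (!is.null(in_path[[as.character(ch$index)]])) break  # revisit
      idx <- c(idx, ch$index)
      ori <- c(ori, ch$orient)
      assign(as.character(ch$index), TRUE, envir = in_path)
      cur <- ch$index; cur_o <- ch$orient
    }
    list(index = idx, orient = ori)
  }

  fwd <- extend("+")
  bwd <- extend("-")
  idx <- c(rev(bwd$index), s, fwd$index)
  ori <- c(rev(flip_orient(bwd$orient)), "+", fwd$orient)
  make_contig(graph, idx, ori)
}

#' Consensus walk from a seed node
#'
#' Extends a contig path bidirectionally from the seed (normally a
#' component's highest-coverage node), applying [choose_branch_mc()] at
#' every step. Traversal stops at a tip (dead end), when the chosen branch
#' leads to a node already in the path (repeat regions), or when no branch
#' meets the coverage floor.
#'
#' @param graph A `dbg_graph`.
#' @param seed Canonical k-mer of the seed node; its coverage must meet the
#'   floor.
#' @param min_coverage Coverage floor for branches.
#' @param lookahead Bubble-detection horizon (nodes).
#' @param exclude Optional logical vector of nodes to treat as absent.
#' @return A [contig_path()].
#' @export
walk_consensus <- function(graph, seed, min_coverage = 2, lookahead = 64L,
                           exclude = NULL) {
  chooser <- function(graph, index, orient, min_coverage, exclude = NULL) {
    choose_branch_mc(graph, index, orient, min_coverage, lookahead, exclude)
  }
  walk_engine(graph, seed, min_coverage, chooser, exclude)
}

#' Explore local variants around a consensus path
#'
#' Walks along a consensus contig and, at every node, follows each
#' qualifying off-path branch depth-first (taking the highest-coverage node
#' at any subsequent branch, cycle-safe, bounded by `max_alt_length`). A
#' walk that returns to the original path at a strictly later position is a
#' local variant -- typically the other allele of a SNP or small indel --
#' and is recorded as an alternative path segment anchored to the consensus
#' segment by two junction edges with k-1 base overlaps. Exploration then
#' resumes from where the alternative rejoins the path. Off-path branches
#' are taken in the path's walk orientation; the same bubble seen from the
#' opposite strand would only duplicate each alternative as its reverse
#' complement, so reverse-orientation branches are not re-explored.
#'
#' @param graph A `dbg_graph`.
#' @param path A [contig_path()] from [walk_consensus()].
#' @param min_coverage Branch coverage floor.
#' @param max_alt_length Maximum alternative-walk length in nodes.
#' @param name Segment id for the consensus sequence.
#' @param exclude Optional logical node filter.
#' @return A [sequence_graph_doc()] with the consensus segment, one segment
#'   per alternative path, junction edges, and one named path per walk.
#' @export
explore_local_variants <- function(graph, path, min_coverage = 2,
                                   max_alt_length = 500L, name = "c1",
                                   exclude = NULL) {
  k <- graph$k
  idx <- match(path$kmers, graph$kmers)
  n <- length(idx)
  pos_of <- new.env(hash = TRUE, parent = emptyenv())
  for (p in seq_len(n)) assign(as.character(idx[p]), p, envir = pos_of)

  segments <- data.frame(id = name, sequence = path$sequence,
                         coverage = mean(path$coverages),
                         stringsAsFactors = FALSE)
  edges <- NULL
  paths <- stats::setNames(list(name), "consensus")
  n_alt <- 0L

  i <- 1L
  while (i <= n) {
    jumped <- FALSE
    if (i < n) {
      nb <- neighbors(graph, idx[i], path$orients[i], exclude)
      nb <- nb[nb$coverage >= min_coverage & nb$index != idx[i + 1L], ,
               drop = FALSE]
      join_max <- i
      for (r in seq_len(nrow(nb))) {
        alt <- follow_alternative(graph, nb$index[r], nb$orient[r],
                                  pos_of, i, min_coverage, max_alt_length,
                                  exclude)
        if (is.null(alt)) next
        n_alt <- n_alt + 1L
        aid <- sprintf("%s_alt_%d", name, n_alt)
        walk_idx <- c(idx[i], alt$index)
        walk_ori <- c(path$orients[i], alt$orient)
        spelled <- spell_steps(graph, walk_idx, walk_ori)
        # trim one base each side: the remainder overlaps the consensus by
        # exactly k-1 bases at both junctions
        aseq <- substr(spelled, 2L, nchar(spelled) - 1L)
        alen <- nchar(aseq)
        j <- alt$join_pos
        internal <- alt$index[-length(alt$index)]
        acov <- if (length(internal)) mean(graph$cov[internal]) else
          graph$cov[alt$index[1L]]
        segments <- rbind(segments, data.frame(
          id = aid, sequence = aseq, coverage = acov,
          stringsAsFactors = FALSE))
        edges <- rbind(edges, data.frame(
          from = c(name, aid), to = c(aid, name),
          from_beg = c(i, alen - (k - 1L)),
          from_end = c(i + k - 1L, alen),
          to_beg = c(0L, j - 1L),
          to_end = c(k - 1L, j + k - 2L),
          stringsAsFactors = FALSE))
        paths[[sprintf("alt_%d", n_alt)]] <- aid
        join_max <- max(join_max, j)
      }
      if (join_max > i) {
        i <- join_max
        jumped <- TRUE
      }
    }
    if (!jumped) i <- i + 1L
  }
  sequence_graph_doc(segments, edges, paths, k = k)
}

# Depth-first greedy walk off the path from a branch target; success when
# it returns to a path node at a position strictly after the branch point.
# Returns NULL on dead end, length bound, cycle, or re-entry at or before
# the branch point (an inversion, not a bubble).
follow_alternative <- function(graph, start_idx, start_orient, pos_of,
                               branch_pos, min_coverage, max_alt_length,
                               exclude = NULL) {
  idx <- integer(0); ori <- character(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cur <- start_idx; cur_o <- start_orient
  repeat {
    p <- pos_of[[as.character(cur)]]
    if (!is.null(p)) {
      if (p > branch_pos) {
        return(list(index = c(idx, cur), orient = c(ori, cur_o),
                    join_pos = p))
      }
      return(NULL)
    }
    if (length(idx) >= max_alt_length) return(NULL)
    idx <- c(idx, cur); ori <- c(ori, cur_o)
    assign(as.character(cur), TRUE, envir = seen)
    nb <- neighbors(graph, cur, cur_o, exclude)
    nb <- nb[nb$coverage >= min_coverage, , drop = FALSE]
    nb <- nb[is.na(mget(as.character(nb$index), envir = seen,
                        ifnotfound = NA)), , drop = FALSE]
    if (!nrow(nb)) return(NULL)
    best <- which(nb$coverage == max(nb$coverage))[1L]
    cur <- nb$index[best]; cur_o <- nb$orient[best]
  }
}

#' Assemble contigs with the consensus algorithm
#'
#' Iterates over nodes in deterministic (sorted k-mer) order. For each node
#' not yet consumed, its connected component is scanned; sufficiently large
#' components are traversed with [walk_consensus()] starting at the
#' component's highest-coverage node, and local variants are explored into
#' a sequence graph. By default the whole component is then consumed, one
#' contig per component. With `multiple_contigs = TRUE` only the path's own
#' nodes are consumed and the rest of the component is reconsidered,
#' yielding multiple contigs per component -- useful when disparate species
#' share k-mers and the graph collapses into one giant component.
#'
#' Contigs shorter than the FASTA length floor are still returned here (and
#' their nodes consumed); [write_contigs_fasta()] applies the length filter
#' at output time.
#'
#' @param graph A `dbg_graph` (pruned or raw).
#' @param min_coverage Coverage floor for seeds and branches.
#' @param multiple_contigs Consume only path nodes instead of whole
#'   components.
#' @param explore_variants Emit one sequence-graph document per contig.
#' @param lookahead Bubble-detection horizon (nodes).
#' @param max_alt_length Alternative-walk bound (nodes).
#' @param min_component Minimum component size (nodes) to traverse.
#' @return A list with `contigs` (list of [contig_path()]) and `docs`
#'   (list of [sequence_graph_doc()], empty unless `explore_variants`).
#' @export
assemble_mc <- function(graph, min_coverage = 2, multiple_contigs = FALSE,
                        explore_variants = TRUE, lookahead = 64L,
                        max_alt_length = 500L, min_component = 2L) {
  consumed <- !graph$alive
  contigs <- list()
  docs <- list()
  for (i in seq_along(graph$kmers)) {   # kmers are stored sorted
    if (consumed[i]) next
    comp <- component_scan(graph, graph$kmers[i], exclude = consumed)
    comp_idx <- match(comp$nodes, graph$kmers)
    if (comp$size < min_component ||
        graph$cov[match(comp$seed, graph$kmers)] < min_coverage) {
      consumed[comp_idx] <- TRUE
      next
    }
    ct <- walk_consensus(graph, comp$seed, min_coverage, lookahead,
                         exclude = consumed)
    contigs[[length(contigs) + 1L]] <- ct
    if (explore_variants) {
      docs[[length(docs) + 1L]] <-
        explore_local_variants(graph, ct, min_coverage, max_alt_length,
                               name = sprintf("c%d", length(contigs)),
                               exclude = consumed)
    }
    if (multiple_contigs) {
      consumed[match(ct$kmers, graph$kmers)] <- TRUE
    } else {
      consumed[comp_idx] <- TRUE
    }
  }
  list(contigs = contigs, docs = docs)
}

#' Extract unitigs (PerfectPath mode)
#'
#' Emits the maximal non-branching paths of the graph: every inner node of
#' a unitig has exactly one incoming and one outgoing edge. Unitigs are
#' node-disjoint and jointly cover every node meeting the coverage floor.
#'
#' @param graph A `dbg_graph`.
#' @param min_coverage Coverage floor; nodes below it are ignored.
#' @return List of [contig_path()] objects.
#' @export
assemble_unitigs <- function(graph, min_coverage = 2) {
  qual <- graph$alive & graph$cov >= min_coverage
  skip <- !qual
  assigned <- rep(FALSE, length(graph$kmers))
  out <- list()

  uniq_next <- function(i, o, taken) {
    nb <- neighbors(graph, i, o, exclude = skip)
    if (nrow(nb) != 1L) return(NULL)
    j <- nb$index[1L]; o2 <- nb$orient[1L]
    if (taken[j]) return(NULL)
    if (node_degree(graph, j, flip_orient(o2), exclude = skip) != 1L) {
      return(NULL)
    }
    list(index = j, orient = o2)
  }

  for (i in seq_along(graph$kmers)) {
    if (!qual[i] || assigned[i]) next
    idx <- i; ori <- "+"
    repeat {  # extend forward
      nxt <- uniq_next(idx[length(idx)], ori[length(ori)],
                       assigned | (seq_along(assigned) %in% idx))
      if (is.null(nxt)) break
      idx <- c(idx, nxt$index); ori <- c(ori, nxt$orient)
    }
    repeat {  # extend backward from the start node
      nxt <- uniq_next(idx[1L], flip_orient(ori[1L]),
                       assigned | (seq_along(assigned) %in% idx))
      if (is.null(nxt)) break
      idx <- c(nxt$index, idx); ori <- c(flip_orient(nxt$orient), ori)
    }
    assigned[idx] <- TRUE
    out[[length(out) + 1L]] <- make_contig(graph, idx, ori)
  }
  out
}
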