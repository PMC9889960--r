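## Subtractive Walk (SW): repeated maximum-coverage walks with per-node
## variant-count estimation from the normalized coverage-change statistic,
## and linearly interpolated coverage subtraction so that nodes shared
## between variants can be traversed once per variant.

#' Normalized coverage change between adjacent path nodes
#'
#' `delta = (c_current - c_previous) / max(c_current, c_previous)`, a value
#' in `[-1, 1]` whose sign follows the coverage change. Along a path, a
#' magnitude close to 0 means the two k-mers co-occur everywhere; a large
#' magnitude flags a junction where coverage steps between a shared region
#' and a variant-specific one.
#'
#' @param c_previous,c_current Positive coverages (vectorised).
#' @return Numeric in `[-1, 1]`.
#' @examples
#' compute_delta(10, 2)   # -0.8
#' compute_delta(2, 10)   # +0.8
#' @export
compute_delta <- function(c_previous, c_current) {
  if (any(c_previous <= 0) || any(c_current <= 0)) {
    stop("coverages must be positive")
  }
  (c_current - c_previous) / pmax(c_current, c_previous)
}

#' Position of the minimal-coverage node
#'
#' The subtractive walk anchors variant counting at the lowest-coverage
#' node of the path, assumed to carry exactly one variant. When several
#' nodes tie at the minimum, the one closest to the end of the path is
#' used.
#'
#' @param coverages Non-empty numeric vector of positive coverages.
#' @return Integer index (1-based) of the last minimum.
#' @export
select_min_node <- function(coverages) {
  if (!length(coverages)) stop("empty coverage list")
  max(which(coverages == min(coverages)))
}

#' Estimate the number of variants covering each path node
#'
#' Starting from the minimal-coverage node (assigned one variant), the
#' path is walked outward in both directions; at each step delta is
#' computed between the previous node of the walk and the current one. A
#' sharp coverage rise (`delta > delta_sw`) means the walk is entering a
#' region shared by one more variant, so the count increments; a sharp
#' drop (`delta < -delta_sw`) decrements it (floored at 1); otherwise the
#' count carries over. Comparisons are strict, so `delta == delta_sw`
#' exactly does not trigger.
#'
#' `as_printed = TRUE` applies the opposite sign pairing (drop increments,
#' rise decrements). With counting anchored at the coverage minimum, that
#' pairing assigns extra variants to the low-coverage flanks rather than
#' to the high-coverage shared core; the default pairing is the one under
#' which shared nodes retain residual coverage after subtraction while
#' variant-specific nodes are zeroed. Both are exposed so the divergence
#' is observable.
#'
#' @param coverages Positive per-position coverages of a path.
#' @param delta_sw Threshold in (0, 1]; default 0.8. Use smaller values
#'   (e.g. 0.4) to capture high strain diversity, values near 1 to keep
#'   only dominant strains.
#' @param as_printed Use the alternative sign pairing (see Details).
#' @return Integer vector of per-position variant counts, all >= 1, with 1
#'   at the minimum position.
#' @examples
#' estimate_variant_counts(c(10, 10, 30, 30, 10, 8), delta_sw = 0.4)
#' @export
estimate_variant_counts <- function(coverages, delta_sw = 0.8,
                                    as_printed = FALSE) {
  stopifnot(delta_sw > 0, delta_sw <= 1)
  n <- length(coverages)
  m <- select_min_node(coverages)
  counts <- integer(n)
  counts[m] <- 1L
  step_count <- function(prev_count, d) {
    up <- if (as_printed) d < -delta_sw else d > delta_sw
    down <- if (as_printed) d > delta_sw else d < -delta_sw
    if (up) prev_count + 1L
    else if (down) max(prev_count - 1L, 1L)
    else prev_count
  }
  if (m < n) {
    for (p in (m + 1L):n) {
      d <- compute_delta(coverages[p - 1L], coverages[p])
      counts[p] <- step_count(counts[p - 1L], d)
    }
  }
  if (m > 1L) {
    for (p in (m - 1L):1L) {
      # the "previous" node is the one visited at the preceding step of
      # this leftward walk, i.e. the position to the right
      d <- compute_delta(coverages[p + 1L], coverages[p])
      counts[p] <- step_count(counts[p + 1L], d)
    }
  }
  counts
}

#' Per-position subtraction amounts
#'
#' Positions with one variant lose their full coverage (they belong to
#' this path alone). Positions with more than one variant lose an amount
#' linearly interpolated, by path index, between the coverages of the
#' nearest single-variant positions before and after -- the walk's best
#' estimate of this variant's own contribution to the shared region. If
#' one side has no single-variant position, the other side's coverage is
#' used as a constant.
#'
#' @param coverages Per-position coverages.
#' @param counts Per-position variant counts from
#'   [estimate_variant_counts()].
#' @return Numeric vector of non-negative subtraction amounts.
#' @export
subtraction_amounts <- function(coverages, counts) {
  stopifnot(length(coverages) == length(counts), all(counts >= 1L))
  n <- length(coverages)
  amounts <- numeric(n)
  ones <- which(counts == 1L)
  for (p in seq_len(n)) {
    if (counts[p] == 1L) {
      amounts[p] <- coverages[p]
    } else {
      b <- ones[ones < p]
      a <- ones[ones > p]
      b <- if (length(b)) max(b) else NA_integer_
      a <- if (length(a)) min(a) else NA_integer_
      if (is.na(b) && is.na(a)) {
        amounts[p] <- 0  # unreachable: the minimum position has count 1
      } else if (is.na(b)) {
        amounts[p] <- coverages[a]
      } else if (is.na(a)) {
        amounts[p] <- coverages[b]
      } else {
        amounts[p] <- coverages[b] +
          (coverages[a] - coverages[b]) * (p - b) / (a - b)
      }
    }
  }
  pmin(amounts, coverages)
}

#' Subtract a walked path's coverage from the graph
#'
#' Applies [subtraction_amounts()] to the graph nodes of a walked path:
#' single-variant nodes drop to coverage 0 (and will not seed or qualify
#' again), shared nodes keep a positive, possibly fractional, residual so
#' later walks can traverse them once per remaining variant.
#'
#' @param graph A `dbg_graph`; coverage is modified in place.
#' @param path A [contig_path()].
#' @param counts Optional precomputed variant counts; by default
#'   recomputed from the path's coverage profile.
#' @param delta_sw,as_printed Passed to [estimate_variant_counts()].
#' @return Invisibly, a list with `counts`, `amounts` and `min_index`
#'   (the anchoring minimal-coverage position).
#' @export
subtract_path_coverage <- function(graph, path, counts = NULL,
                                   delta_sw = 0.8, as_printed = FALSE) {
  idx <- match(path$kmers, graph$kmers)
  if (anyNA(idx)) stop("path node missing from graph")
  cov <- graph$cov[idx]
  if (is.null(counts)) {
    counts <- estimate_variant_counts(cov, delta_sw, as_printed)
  }
  amounts <- subtraction_amounts(cov, counts)
  graph$cov[idx] <- pmax(cov - amounts, 0)
  invisible(list(counts = counts, amounts = amounts,
                 min_index = select_min_node(cov)))
}

#' Maximum-coverage walk
#'
#' Like [walk_consensus()] but with the bubble rule disregarded: at every
#' branch the highest-coverage branch meeting the floor is taken (ties in
#' base order). Stop conditions are the same: dead end, revisit, or no
#' qualifying branch.
#'
#' @inheritParams walk_consensus
#' @return A [contig_path()].
#' @export
walk_max_coverage <- function(graph, seed, min_coverage = 2,
                              exclude = NULL) {
  walk_engine(graph, seed, min_coverage, choose_branch_greedy, exclude)
}

#' Assemble contigs with the subtractive walk
#'
#' Repeatedly: find a node meeting the coverage floor (deterministic sorted
#' order), locate a locally maximal-coverage seed by a budget-bounded
#' component scan, extract the maximum-coverage path through it, record it
#' as a contig, then estimate per-node variant counts and subtract the
#' path's interpolated coverage from the graph. Because single-variant
#' nodes drop to zero while shared cores keep a residual, a region shared
#' by several strains is re-traversed once per strain and appears in
#' several output contigs. The loop ends when no node meets the floor;
#' every iteration zeroes at least one previously positive node, so
#' termination is guaranteed even on cyclic graphs.
#'
#' A walk whose sequence equals (or is the reverse complement of) an
#' already emitted contig is subtracted but not re-emitted: re-walks of a
#' residual shared core can reproduce a path verbatim.
#'
#' @param graph A `dbg_graph`; consumed (coverage driven to < floor) by
#'   the run. Use [copy_graph()] to keep the original.
#' @param min_coverage Coverage floor for seeds and branches.
#' @param delta_sw Variant-count threshold (see
#'   [estimate_variant_counts()]).
#' @param as_printed Alternative sign pairing for variant counting.
#' @param search_budget Component-scan budget (nodes) when locating the
#'   locally maximal seed.
#' @return List of [contig_path()] objects.
#' @export
assemble_sw <- function(graph, min_coverage = 2, delta_sw = 0.8,
                        as_printed = FALSE, search_budget = 1000L) {
  contigs <- list()
  seen_seq <- new.env(hash = TRUE, parent = emptyenv())
  max_iter <- 2L * sum(graph$alive & graph$cov > 0) + 10L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("subtractive walk failed to converge (internal error)")
    }
    live <- which(graph$alive & graph$cov >= min_coverage)
    if (!length(live)) break
    start <- live[1L]  # kmers sorted => deterministic
    comp <- component_scan(graph, graph$kmers[start],
                           budget = search_budget,
                           exclude = graph$cov < min_coverage)
    total_before <- sum(graph$cov[graph$alive])
    ct <- walk_max_coverage(graph, comp$seed, min_coverage)
    subtract_path_coverage(graph, ct, delta_sw = delta_sw,
                           as_printed = as_printed)
    if (sum(graph$cov[graph$alive]) >= total_before) {
      stop("subtractive walk made no progress (internal error)")
    }
    key <- min(ct$sequence, revcomp(ct$sequence))
    if (is.null(seen_seq[[key]])) {
      assign(key, TRUE, envir = seen_seq)
      contigs[[length(contigs) + 1L]] <- ct
    }
  }
  contigs
}
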