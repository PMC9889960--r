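## Strain-specific contig reconstruction from a sequence graph plus a
## per-segment, per-strain mapping-score table. At every junction of the
## consensus backbone the branch whose sequence scores highest for the
## strain is taken; ambiguity (a tie, or no scored candidate) falls back to
## the backbone's own branch.

#' Branch score from mapping identity and query cover
#'
#' The score of a segment for a strain is the mapping identity multiplied
#' by the proportion of the alignment covering the query segment.
#'
#' @param identity Fraction in `[0, 1]`.
#' @param query_cover Fraction in `[0, 1]`.
#' @return The product, in `[0, 1]`.
#' @examples
#' branch_score(0.97, 0.90)
#' @export
branch_score <- function(identity, query_cover) {
  if (any(identity < 0 | identity > 1) ||
      any(query_cover < 0 | query_cover > 1)) {
    stop("identity and query cover must lie in [0, 1]")
  }
  identity * query_cover
}

#' Read a segment-to-strain score table
#'
#' Tab-separated columns: `segment`, `strain`, `identity`, `query_cover`
#' (header optional, detected). In practice such a table is derived from
#' mapping each graph segment against a database of reference genomes;
#' any aligner's identity and query-coverage output fits.
#'
#' @param path TSV file.
#' @return A `segment_scores` data frame.
#' @export
read_score_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("segment", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:4] <- c("segment", "strain", "identity", "query_cover")
  }
  segment_scores(df)
}

#' @rdname read_score_table
#' @param df Data frame with columns `segment`, `strain`, `identity`,
#'   `query_cover`. Missing (segment, strain) pairs mean "no mapping", not
#'   a zero score.
#' @export
segment_scores <- function(df) {
  stopifnot(all(c("segment", "strain", "identity", "query_cover") %in%
                  names(df)))
  branch_score(df$identity, df$query_cover)  # validates ranges
  structure(df, class = c("segment_scores", "data.frame"))
}

# Score of a segment for a strain; NA when no entry exists.
lookup_score <- function(scores, segment, strain) {
  hit <- scores$segment == segment & scores$strain == strain
  if (!any(hit)) return(NA_real_)
  branch_score(scores$identity[hit][1L], scores$query_cover[hit][1L])
}

#' Score graph segments against reference strain sequences
#'
#' Fixture/offline helper standing in for an external aligner: each
#' segment is aligned locally (both strands) against each reference with
#' [Biostrings::pairwiseAlignment()]; identity is the percent identity of
#' the best local alignment and query cover the aligned fraction of the
#' segment. A segment occurring exactly (either strand) in a reference
#' scores identity 1, cover 1 without alignment.
#'
#' @param doc A [sequence_graph_doc()].
#' @param references Named character vector of strain sequences.
#' @return A `segment_scores` data frame.
#' @export
score_segments <- function(doc, references) {
  stopifnot(!is.null(names(references)))
  rows <- list()
  for (sid in doc$segments$id) {
    s <- doc$segments$sequence[doc$segments$id == sid]
    for (st in names(references)) {
      ref <- references[[st]]
      if (grepl(s, ref, fixed = TRUE) || grepl(revcomp(s), ref,
                                               fixed = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          segment = sid, strain = st, identity = 1, query_cover = 1,
          stringsAsFactors = FALSE)
      } else {
        best <- NULL
        for (q in c(s, revcomp(s))) {
          aln <- Biostrings::pairwiseAlignment(
            pattern = q, subject = ref, type = "local")
          cand <- list(identity = Biostrings::pid(aln) / 100,
                       cover = nchar(
                         gsub("-", "",
                              as.character(Biostrings::alignedPattern(aln)))
                       ) / nchar(q))
          if (is.null(best) ||
              cand$identity * cand$cover > best$identity * best$cover) {
            best <- cand
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          segment = sid, strain = st, identity = best$identity,
          query_cover = min(best$cover, 1), stringsAsFactors = FALSE)
      }
    }
  }
  segment_scores(do.call(rbind, rows))
}

# Alternatives of a backbone segment, ordered by branch position: for each
# non-backbone segment, its entry edge (backbone -> alt) and exit edge
# (alt -> backbone) give the junction coordinates on the backbone.
backbone_alternatives <- function(doc, backbone_seg) {
  ed <- doc$edges
  alts <- setdiff(doc$segments$id, backbone_seg)
  out <- list()
  for (aid in alts) {
    ein <- which(ed$from == backbone_seg & ed$to == aid)
    eout <- which(ed$from == aid & ed$to == backbone_seg)
    if (!length(ein) || !length(eout)) next  # not a simple bubble
    out[[length(out) + 1L]] <- data.frame(
      id = aid,
      branch_beg = ed$from_beg[ein[1L]],
      branch_end = ed$from_end[ein[1L]],
      rejoin_beg = ed$to_beg[eout[1L]],
      rejoin_end = ed$to_end[eout[1L]],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(id = character(0), branch_beg = integer(0),
                      branch_end = integer(0), rejoin_beg = integer(0),
                      rejoin_end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$branch_beg, res$id), , drop = FALSE]
}

#' Walk a sequence graph for one strain
#'
#' Walks along the named backbone path; at every junction where an
#' alternative path diverges, the branch (alternative segment vs the
#' backbone's own continuation) with the highest [branch_score()] for the
#' strain is taken. A tie, or the absence of any scored candidate, keeps
#' the backbone branch. Overlapping alternatives are resolved greedily in
#' walk order: once a branch is taken, junctions before its rejoin point
#' are passed over.
#'
#' @param doc A [sequence_graph_doc()] as produced by
#'   [explore_local_variants()] (single-segment backbone plus alternative
#'   bubble segments).
#' @param scores A `segment_scores` table.
#' @param strain Strain id to walk for.
#' @param backbone Name of the backbone path (default `"consensus"`).
#' @return The spelled strain sequence (k-1 overlaps collapsed).
#' @export
walk_strain <- function(doc, scores, strain, backbone = "consensus") {
  bp <- doc$paths[[backbone]]
  if (is.null(bp)) stop("no such backbone path: ", backbone)
  if (length(bp) != 1L) {
    stop("backbone path must be a single segment; got ", length(bp))
  }
  bseq <- doc$segments$sequence[doc$segments$id == bp]
  k <- doc$k
  alts <- backbone_alternatives(doc, bp)
  bscore <- lookup_score(scores, bp, strain)

  out <- character(0)
  pos <- 1L  # next backbone base (1-based) not yet emitted
  for (r in seq_len(nrow(alts))) {
    if (alts$branch_beg[r] + 1L < pos) next  # inside a chosen alternative
    ascore <- lookup_score(scores, alts$id[r], strain)
    take_alt <- !is.na(ascore) && (is.na(bscore) || ascore > bscore)
    if (!take_alt) next
    aseq <- doc$segments$sequence[doc$segments$id == alts$id[r]]
    if (alts$rejoin_beg[r] + 1L <= alts$branch_end[r]) {
      stop("inconsistent junction for alternative ", alts$id[r],
           ": rejoin precedes branch point")
    }
    # backbone through the entry overlap, then the alternative's middle
    out <- c(out, substr(bseq, pos, alts$branch_end[r]),
             substr(aseq, k, nchar(aseq) - (k - 1L)))
    pos <- alts$rejoin_beg[r] + 1L  # resume at the exit overlap
  }
  out <- c(out, substr(bseq, pos, nchar(bseq)))
  paste(out, collapse = "")
}

#' Strain-level contigs for a set of strains
#'
#' One [walk_strain()] per strain, deterministically.
#'
#' @inheritParams walk_strain
#' @param strains Character vector of strain ids.
#' @return Named character vector of strain contig sequences.
#' @export
extract_strain_contigs <- function(doc, scores, strains,
                                   backbone = "consensus") {
  stats::setNames(
    vapply(strains, function(st) walk_strain(doc, scores, st, backbone),
           character(1)),
    strains)
}

#' Write strain contigs to FASTA
#'
#' Multi-FASTA with the strain id and length in each header, 80-column
#' wrapped, in the given strain order.
#'
#' @param contigs Named character vector from [extract_strain_contigs()].
#' @param path Output file.
#' @return Number of records written, invisibly.
#' @export
write_strain_fasta <- function(contigs, path) {
  lines <- character(0)
  for (st in names(contigs)) {
    s <- contigs[[st]]
    starts <- seq(1L, nchar(s), by = 80L)
    lines <- c(lines,
               sprintf(">strain_%s length=%d", st, nchar(s)),
               substring(s, starts, pmin(starts + 79L, nchar(s))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(length(contigs))
}
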