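#' Sequence graph documents
#'
#' The serializable representation of a contig together with its local
#' variation: segments (with mean coverage), edges joining segments with a
#' k-1 base overlap, and named ordered walks (the consensus path and each
#' alternative path). Edge coordinates are 0-based half-open intervals on
#' each segment; for the documents this assembler produces, an alternative
#' segment overlaps the consensus segment by exactly k-1 bases at both of
#' its junctions.
#'
#' @param segments Data frame with columns `id`, `sequence`, `coverage`.
#' @param edges Data frame with columns `from`, `to`, `from_beg`,
#'   `from_end`, `to_beg`, `to_end` (0-based, end-exclusive).
#' @param paths Named list of character vectors of segment ids.
#' @param k The k-mer size the graph was built at (junction overlaps are
#'   k-1 bases).
#' @return A `sequence_graph_doc` object.
#' @export
sequence_graph_doc <- function(segments, edges = NULL, paths = list(), k) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        from_beg = integer(0), from_end = integer(0),
                        to_beg = integer(0), to_end = integer(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence", "coverage") %in% names(segments)))
  if (anyDuplicated(segments$id)) {
    stop("duplicate segment id: ",
         segments$id[duplicated(segments$id)][1L])
  }
  missing <- setdiff(c(edges$from, edges$to), segments$id)
  if (length(missing)) {
    stop("edge references unknown segment: ", missing[1L])
  }
  ov <- c(edges$from_end - edges$from_beg, edges$to_end - edges$to_beg)
  if (length(ov) && any(ov != k - 1L)) {
    stop("junction overlap must be k-1 = ", k - 1L, " bases")
  }
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!all(p %in% segments$id)) {
      stop("path ", nm, " references unknown segment")
    }
    if (length(p) > 1L) {
      for (s in seq_len(length(p) - 1L)) {
        hit <- edges$from == p[s] & edges$to == p[s + 1L]
        if (!any(hit)) {
          stop("path ", nm, " is not a connected walk: no edge ",
               p[s], " -> ", p[s + 1L])
        }
      }
    }
  }
  structure(list(segments = segments, edges = edges, paths = paths,
                 k = as.integer(k)),
            class = "sequence_graph_doc")
}

#' @export
print.sequence_graph_doc <- function(x, ...) {
  cat(sprintf("sequence graph: %d segments, %d edges, %d paths (k = %d)\n",
              nrow(x$segments), nrow(x$edges), length(x$paths), x$k))
  invisible(x)
}

#' Spell the sequence of a named path
#'
#' Concatenates the path's segments, collapsing the k-1 base overlap at
#' every junction.
#'
#' @param doc A [sequence_graph_doc()].
#' @param name Path name.
#' @return The spelled DNA sequence.
#' @export
doc_path_sequence <- function(doc, name) {
  p <- doc$paths[[name]]
  if (is.null(p)) stop("no such path: ", name)
  seqs <- doc$segments$sequence[match(p, doc$segments$id)]
  out <- seqs[1L]
  for (s in seqs[-1L]) out <- paste0(out, substring(s, doc$k))
  out
}

# GFA2 position with end-of-segment sentinel.
gfa2_pos <- function(pos, seglen) {
  ifelse(pos == seglen, paste0(pos, "$"), as.character(pos))
}

#' Write a sequence graph as GFA2
#'
#' Emits a header (`H  VN:Z:2.0` plus a `ks:i:` tag recording k), one `S`
#' line per segment (with mean coverage as a `DP:f:` tag), one `E` line per
#' junction edge with the k-1 base overlap coordinates, and one `O`
#' (ordered group) line per path. Output is byte-deterministic for equal
#' documents, and `read_gfa2(write_gfa2(doc))` is the identity for files
#' produced here.
#'
#' @param doc A [sequence_graph_doc()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_gfa2 <- function(doc, path) {
  stopifnot(inherits(doc, "sequence_graph_doc"))
  lines <- sprintf("H\tVN:Z:2.0\tks:i:%d", doc$k)
  sg <- doc$segments
  lines <- c(lines, sprintf("S\t%s\t%d\t%s\tDP:f:%.2f", sg$id,
                            nchar(sg$sequence), sg$sequence, sg$coverage))
  ed <- doc$edges
  if (nrow(ed)) {
    flen <- nchar(sg$sequence[match(ed$from, sg$id)])
    tlen <- nchar(sg$sequence[match(ed$to, sg$id)])
    lines <- c(lines, sprintf("E\t*\t%s+\t%s+\t%s\t%s\t%s\t%s\t*",
                              ed$from, ed$to,
                              gfa2_pos(ed$from_beg, flen),
                              gfa2_pos(ed$from_end, flen),
                              gfa2_pos(ed$to_beg, tlen),
                              gfa2_pos(ed$to_end, tlen)))
  }
  for (nm in names(doc$paths)) {
    lines <- c(lines, sprintf("O\t%s\t%s", nm,
                              paste0(doc$paths[[nm]], "+", collapse = " ")))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

strip_pos <- function(x) as.integer(sub("\\$$", "", x))

#' Read a GFA2 sequence graph
#'
#' Parses `S`, `E` and `O` lines as produced by [write_gfa2()]; unknown
#' line types are skipped with a warning (tolerant reader). An `E` line
#' naming an absent segment is an error.
#'
#' @param path A GFA2 file.
#' @return A [sequence_graph_doc()].
#' @export
read_gfa2 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(fields, `[[`, character(1), 1L)

  k <- NA_integer_
  h <- fields[types == "H"]
  if (length(h)) {
    tags <- unlist(h)
    ks <- grep("^ks:i:", tags, value = TRUE)
    if (length(ks)) k <- as.integer(sub("^ks:i:", "", ks[1L]))
  }

  seg_rows <- fields[types == "S"]
  segments <- data.frame(
    id = vapply(seg_rows, `[[`, character(1), 2L),
    sequence = vapply(seg_rows, `[[`, character(1), 4L),
    coverage = vapply(seg_rows, function(f) {
      dp <- grep("^DP:f:", f, value = TRUE)
      if (length(dp)) as.numeric(sub("^DP:f:", "", dp[1L])) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)

  edge_rows <- fields[types == "E"]
  edges <- data.frame(
    from = vapply(edge_rows, function(f) sub("[+-]$", "", f[[3L]]),
                  character(1)),
    to = vapply(edge_rows, function(f) sub("[+-]$", "", f[[4L]]),
                character(1)),
    from_beg = vapply(edge_rows, function(f) strip_pos(f[[5L]]), integer(1)),
    from_end = vapply(edge_rows, function(f) strip_pos(f[[6L]]), integer(1)),
    to_beg = vapply(edge_rows, function(f) strip_pos(f[[7L]]), integer(1)),
    to_end = vapply(edge_rows, function(f) strip_pos(f[[8L]]), integer(1)),
    stringsAsFactors = FALSE)
  bad <- setdiff(c(edges$from, edges$to), segments$id)
  if (length(bad)) {
    stop("E line references unknown segment ", sQuote(bad[1L]),
         " in ", path)
  }

  path_rows <- fields[types == "O"]
  paths <- lapply(path_rows, function(f) {
    sub("[+-]$", "", strsplit(f[[3L]], " ", fixed = TRUE)[[1L]])
  })
  names(paths) <- vapply(path_rows, `[[`, character(1), 2L)

  unknown <- setdiff(unique(types), c("H", "S", "E", "O"))
  if (length(unknown)) {
    warning("skipping unknown GFA2 line type(s): ",
            paste(unknown, collapse = ", "))
  }
  if (is.na(k)) {
    # infer k from any junction overlap; fall back to 0-overlap sentinel
    k <- if (nrow(edges)) edges$from_end[1L] - edges$from_beg[1L] + 1L else 1L
  }
  sequence_graph_doc(segments, edges, paths, k = k)
}

#' Write a sequence graph as FASTG
#'
#' One record per segment following the FASTG v1.0 draft adjacency syntax:
#' the header names the segment and, colon-separated, its successor
#' segments (comma-separated when several), terminated by a semicolon.
#' Variation is carried by distinct segments (the bracketed inline-variant
#' notation of the draft is not used), matching the GFA2 representation.
#' Records are emitted in segment-id order.
#'
#' @param doc A [sequence_graph_doc()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fastg <- function(doc, path) {
  stopifnot(inherits(doc, "sequence_graph_doc"))
  sg <- doc$segments
  lines <- character(0)
  for (id in sort_c(sg$id)) {
    succ <- sort_c(unique(doc$edges$to[doc$edges$from == id]))
    header <- if (length(succ)) {
      paste0(">", id, ":", paste(succ, collapse = ","), ";")
    } else {
      paste0(">", id, ";")
    }
    s <- sg$sequence[sg$id == id]
    starts <- seq(1L, nchar(s), by = 80L)
    lines <- c(lines, header,
               substring(s, starts, pmin(starts + 79L, nchar(s))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
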