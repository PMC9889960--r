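## Synthetic multi-strain communities: reference genomes, mutated strains
## (SNP/indel), abundance-weighted error-bearing reads, and alignment-free
## assembly evaluation. Everything is driven by one integer seed that fans
## out derivably to per-component generators, so adding one genome does not
## perturb another's reads.

#' Derive a mutated strain from a genome
#'
#' Per-base independent events: a SNP replaces the base with one of the
#' three alternatives uniformly; an indel inserts or deletes (equiprobable)
#' a stretch of 1-3 bases. The applied edits are returned as ground truth.
#' Deterministic under `seed`.
#'
#' @param genome Reference sequence.
#' @param snp_rate,indel_rate Per-base event probabilities in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `sequence` (the strain) and `edits` (data frame with
#'   `pos`, `type` in snp/ins/del, `ref`, `alt`).
#' @export
mutate_strain <- function(genome, snp_rate, indel_rate, seed) {
  if (snp_rate < 0 || snp_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    stop("mutation rates must lie in [0, 1)")
  }
  stopifnot(nchar(genome) >= 1)
  with_local_seed(seed, {
    L <- nchar(genome)
    bases <- strsplit(genome, "")[[1L]]
    edits <- list()

    snp_at <- which(runif(L) < snp_rate)
    for (p in snp_at) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
      edits[[length(edits) + 1L]] <- data.frame(
        pos = p, type = "snp", ref = bases[p], alt = alt,
        stringsAsFactors = FALSE)
      bases[p] <- alt
    }

    indel_at <- which(runif(L) < indel_rate)
    # apply right-to-left so earlier positions stay valid
    pieces <- as.list(bases)
    for (p in rev(indel_at)) {
      len <- sample(3L, 1L)
      if (runif(1) < 0.5) {  # insertion after position p
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        pieces[[p]] <- paste0(pieces[[p]], ins)
        edits[[length(edits) + 1L]] <- data.frame(
          pos = p, type = "ins", ref = "", alt = ins,
          stringsAsFactors = FALSE)
      } else {               # deletion of up to len bases from p
        del_to <- min(p + len - 1L, L)
        ref <- paste(unlist(lapply(pieces[p:del_to], substr, 1L, 1L)),
                     collapse = "")
        for (q in p:del_to) pieces[[q]] <- sub("^.", "", pieces[[q]])
        edits[[length(edits) + 1L]] <- data.frame(
          pos = p, type = "del", ref = ref, alt = "",
          stringsAsFactors = FALSE)
      }
    }
    edits <- if (length(edits)) {
      ed <- do.call(rbind, edits)
      ed[order(ed$pos), , drop = FALSE]
    } else {
      data.frame(pos = integer(0), type = character(0),
                 ref = character(0), alt = character(0))
    }
    list(sequence = paste(unlist(pieces), collapse = ""), edits = edits)
  })
}

#' Define a simulated community
#'
#' Bundles reference genomes, per-genome strain specifications, and read
#' simulation parameters; [simulate_reads()] realises the reads.
#' `simulated_community()` applies [mutate_strain()] immediately, so the
#' returned object carries every final sequence (references and strains)
#' as ground truth.
#'
#' @param genomes Named character vector of reference genomes.
#' @param strains Optional named list: for each genome id, a data frame
#'   with columns `snp_rate`, `indel_rate` (one row per derived strain).
#' @param abundances Named relative weights, one per final sequence
#'   (default 1 for all).
#' @param read_length Read length in bases.
#' @param depth Fold coverage per sequence at weight 1.
#' @param error_rate Per-base substitution error rate of the reads.
#' @param layout `"uniform"` (random start positions) or `"tiling"`
#'   (evenly spaced deterministic starts including both sequence ends).
#' @param seed Master integer seed.
#' @return A `simulated_community` list with `sequences`, `edits`,
#'   `abundances` and the simulation parameters.
#' @export
simulated_community <- function(genomes, strains = NULL, abundances = NULL,
                                read_length = 150L, depth = 30,
                                error_rate = 0, layout = c("uniform",
                                                           "tiling"),
                                seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(!is.null(names(genomes)), error_rate >= 0, error_rate < 1,
            depth > 0, read_length >= 1)
  sequences <- as.list(genomes)
  edits <- list()
  for (gi in seq_along(genomes)) {
    gid <- names(genomes)[gi]
    spec <- strains[[gid]]
    if (is.null(spec)) next
    for (si in seq_len(nrow(spec))) {
      mut <- mutate_strain(genomes[[gid]], spec$snp_rate[si],
                           spec$indel_rate[si],
                           seed = derive_seed(seed, 101L * gi + si))
      sid <- sprintf("%s_strain%d", gid, si)
      sequences[[sid]] <- mut$sequence
      edits[[sid]] <- mut$edits
    }
  }
  if (is.null(abundances)) {
    abundances <- stats::setNames(rep(1, length(sequences)),
                                  names(sequences))
  }
  if (any(abundances <= 0)) stop("abundances must be positive")
  structure(list(sequences = sequences, edits = edits,
                 abundances = abundances, read_length = as.integer(
                   read_length),
                 depth = depth, error_rate = error_rate, layout = layout,
                 seed = as.integer(seed)),
            class = "simulated_community")
}

#' Simulate shotgun reads from a community
#'
#' For each sequence, `ceiling(depth * length / read_length)` reads scaled
#' by the sequence's abundance weight. Uniform layout draws start
#' positions and strands uniformly; tiling layout spaces starts evenly
#' over the sequence (both ends included, forward strand), which
#' guarantees every consecutive k-mer pair is observed -- the idealised
#' read set under which a clean graph spells the genome back exactly.
#' Substitution errors are applied per base at the community's error rate.
#' Byte-identical output for equal seeds.
#'
#' @param community A [simulated_community()].
#' @return Data frame with `id`, `sequence`, `source` columns (same shape
#'   as [read_sequences()] output).
#' @export
simulate_reads <- function(community) {
  stopifnot(inherits(community, "simulated_community"))
  rl <- community$read_length
  out <- vector("list", length(community$sequences))
  for (si in seq_along(community$sequences)) {
    sid <- names(community$sequences)[si]
    s <- community$sequences[[si]]
    L <- nchar(s)
    if (rl > L) {
      stop("read length ", rl, " exceeds sequence length ", L,
           " of ", sid)
    }
    w <- community$abundances[[sid]]
    n <- ceiling(community$depth * L / rl * w)
    out[[si]] <- with_local_seed(derive_seed(community$seed, si), {
      if (community$layout == "tiling") {
        starts <- unique(round(seq(1L, L - rl + 1L, length.out = n)))
        strands <- rep("+", length(starts))
      } else {
        starts <- sample.int(L - rl + 1L, n, replace = TRUE)
        strands <- sample(c("+", "-"), n, replace = TRUE)
      }
      reads <- substring(s, starts, starts + rl - 1L)
      rev <- strands == "-"
      if (any(rev)) reads[rev] <- revcomp(reads[rev])
      if (community$error_rate > 0) {
        reads <- vapply(reads, add_substitution_errors,
                        character(1), rate = community$error_rate,
                        USE.NAMES = FALSE)
      }
      data.frame(
        id = sprintf("%s_read%d", sid, seq_along(reads)),
        sequence = reads,
        source = sprintf("%s:%d%s", sid, starts, strands),
        stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}

add_substitution_errors <- function(read, rate) {
  hits <- which(runif(nchar(read)) < rate)
  if (!length(hits)) return(read)
  b <- strsplit(read, "")[[1L]]
  for (p in hits) {
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  }
  paste(b, collapse = "")
}

#' Write reads as FASTQ
#'
#' Four-line records with a constant maximum quality string (the simulator
#' does not model quality scores).
#'
#' @param reads Data frame from [simulate_reads()].
#' @param path Output file.
#' @return Number of records, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1L, by = 4L, length.out = nrow(reads))] <-
    paste0("@", reads$id)
  lines[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$sequence
  lines[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = nrow(reads))] <-
    vapply(nchar(reads$sequence),
           function(n) strrep("I", n), character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(nrow(reads))
}

#' Alignment-free assembly evaluation
#'
#' Genome fraction per reference: the percentage of reference positions
#' overlapped by at least one k-mer shared (canonically, hence
#' strand-insensitively) with any contig. Exact and dependency-free for
#' error-free fixtures; not numerically comparable to alignment-based
#' evaluation on errorful data. N50 is the largest L such that contigs of
#' length >= L sum to at least half the total assembly length.
#'
#' @param contigs Character vector of contig sequences (or list of
#'   [contig_path()] objects).
#' @param references Character vector of reference sequences.
#' @param k Odd k-mer size, at most the shortest contig length.
#' @return List with `genome_fraction` (numeric vector, percent, one per
#'   reference), `n50` (bases) and `contig_count`.
#' @export
evaluate_assembly <- function(contigs, references, k) {
  if (!length(references)) stop("no reference sequences given")
  if (is.list(contigs) && length(contigs) &&
      inherits(contigs[[1L]], "contig_path")) {
    contigs <- vapply(contigs, `[[`, character(1), "sequence")
  }
  contigs <- as.character(contigs)
  k <- check_k(k)
  if (length(contigs) && any(nchar(contigs) < k)) {
    stop("k exceeds the shortest contig length")
  }
  contig_kmers <- unique(unlist(lapply(contigs, function(s) {
    cw <- canonical_windows(s, k)
    cw$canonical[cw$valid]
  })))

  gf <- vapply(references, function(ref) {
    L <- nchar(ref)
    cw <- canonical_windows(ref, k)
    shared <- which(cw$valid & cw$canonical %in% contig_kmers)
    if (!length(shared)) return(0)
    covered <- IRanges::coverage(IRanges::IRanges(start = shared,
                                                  width = k), width = L)
    100 * sum(covered > 0) / L
  }, numeric(1), USE.NAMES = FALSE)

  lens <- sort(nchar(contigs), decreasing = TRUE)
  n50 <- if (length(lens)) {
    lens[which(cumsum(lens) >= sum(lens) / 2)[1L]]
  } else {
    0L
  }
  list(genome_fraction = gf, n50 = as.integer(n50),
       contig_count = length(contigs))
}

#' Plant a two-strain sequence graph with known truth
#'
#' Builds a [sequence_graph_doc()] directly from a backbone strain and a
#' set of SNP positions: the backbone is strain A's sequence; for each SNP
#' (which must be at least `2k` apart and `k` away from either end) an
#' alternative segment carries strain B's allele with its k-1 base
#' flanking overlaps. The returned truths let a strain walk be checked
#' byte-for-byte.
#'
#' @param backbone Strain A sequence.
#' @param snp_positions Integer positions of planted SNPs.
#' @param k Odd k-mer size for the junction overlaps.
#' @param seed Seed for drawing the alternative alleles.
#' @return List with `doc`, and `strains` (named character vector with
#'   entries `A` and `B`).
#' @export
plant_strain_bubbles <- function(backbone, snp_positions, k, seed = 1L) {
  k <- check_k(k)
  L <- nchar(backbone)
  snp_positions <- sort(unique(as.integer(snp_positions)))
  stopifnot(all(snp_positions > k), all(snp_positions <= L - k),
            all(diff(snp_positions) >= 2L * k))
  bases <- strsplit(backbone, "")[[1L]]
  alt_bases <- with_local_seed(seed, vapply(snp_positions, function(p) {
    sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }, character(1)))
  strain_b <- bases
  strain_b[snp_positions] <- alt_bases
  strain_b <- paste(strain_b, collapse = "")

  segments <- data.frame(id = "c1", sequence = backbone, coverage = 1,
                         stringsAsFactors = FALSE)
  edges <- NULL
  paths <- list(consensus = "c1")
  for (ai in seq_along(snp_positions)) {
    p <- snp_positions[ai]
    aid <- sprintf("c1_alt_%d", ai)
    aseq <- paste0(substr(backbone, p - k + 1L, p - 1L), alt_bases[ai],
                   substr(backbone, p + 1L, p + k - 1L))
    alen <- nchar(aseq)
    segments <- rbind(segments, data.frame(
      id = aid, sequence = aseq, coverage = 1, stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(
      from = c("c1", aid), to = c(aid, "c1"),
      from_beg = c(p - k, alen - (k - 1L)),
      from_end = c(p - 1L, alen),
      to_beg = c(0L, p),
      to_end = c(k - 1L, p + k - 1L),
      stringsAsFactors = FALSE))
    paths[[sprintf("alt_%d", ai)]] <- aid
  }
  list(doc = sequence_graph_doc(segments, edges, paths, k = k),
       strains = c(A = backbone, B = strain_b))
}
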