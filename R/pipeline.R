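#' Assembly run configuration
#'
#' Collects every knob of the workflow with the assembler's conventional
#' defaults: k = 31, minimum coverage 2, tip length 100, subtractive-walk
#' delta 0.8. Unknown option names are an error, so typos fail fast.
#'
#' @param ... Overrides of the default fields: `input_files`, `k`,
#'   `algorithm` (`"MC"`, `"SW"` or `"PerfectPath"`), `min_coverage`,
#'   `tip_length`, `delta_sw`, `as_printed`, `multiple_contigs`,
#'   `min_contig_length`, `lookahead`, `max_alt_length`, `min_component`,
#'   `search_budget`, `output_prefix`, `emit_gfa`, `emit_fastg`,
#'   `save_graph`, `load_graph`, `seed`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    input_files = character(0),
    k = 31L,
    algorithm = "MC",
    min_coverage = 2,
    tip_length = 100L,
    delta_sw = 0.8,
    as_printed = FALSE,
    multiple_contigs = FALSE,
    min_contig_length = 100L,
    lookahead = 64L,
    max_alt_length = 500L,
    min_component = 2L,
    search_budget = 1000L,
    output_prefix = NULL,
    emit_gfa = FALSE,
    emit_fastg = FALSE,
    save_graph = NULL,
    load_graph = NULL,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration option(s): ", paste(unknown,
                                                    collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  if (!cfg$algorithm %in% c("MC", "SW", "PerfectPath")) {
    stop("unknown algorithm ", sQuote(cfg$algorithm),
         "; expected MC, SW or PerfectPath")
  }
  cfg$k <- check_k(cfg$k)
  stopifnot(cfg$min_coverage >= 0, cfg$tip_length >= 0,
            cfg$delta_sw > 0, cfg$delta_sw <= 1)
  structure(cfg, class = "run_config")
}

#' Run the assembly workflow
#'
#' Build (or load/merge) the de Bruijn graph, prune it, traverse with the
#' configured algorithm, and -- when an output prefix is set -- write the
#' contig FASTA, optional GFA2/FASTG sequence graphs (MC only), optional
#' serialized graph, and a tab-separated run manifest. Identical
#' configuration and inputs produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param reads Optional in-memory reads (data frame with `sequence`, as
#'   from [read_sequences()] or [simulate_reads()]); otherwise
#'   `config$input_files` are read.
#' @return Invisibly, a list with `contigs`, `docs`, `graph` and a
#'   `summary` of counts.
#' @export
run_assembly <- function(config, reads = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$load_graph)) {
    graph <- Reduce(merge_graphs, lapply(config$load_graph, load_graph))
    if (graph$k != config$k && length(config$input_files) == 0L &&
        is.null(reads)) {
      config$k <- graph$k
    }
  } else {
    if (is.null(reads)) {
      if (!length(config$input_files)) stop("no input files configured")
      parts <- lapply(config$input_files, read_sequences)
      reads <- do.call(rbind, parts)
    }
    graph <- build_graph(reads, config$k)
  }
  pruned <- prune_graph(graph, config$tip_length, config$min_coverage)
  message(sprintf("graph: %d nodes after pruning (%d tip, %d low-coverage removed)",
                  sum(graph$alive), pruned$tips_removed,
                  pruned$low_coverage_removed))
  if (!is.null(config$save_graph)) save_graph(graph, config$save_graph)

  docs <- list()
  if (config$algorithm == "MC") {
    res <- assemble_mc(graph, min_coverage = config$min_coverage,
                       multiple_contigs = config$multiple_contigs,
                       explore_variants = config$emit_gfa ||
                         config$emit_fastg,
                       lookahead = config$lookahead,
                       max_alt_length = config$max_alt_length,
                       min_component = config$min_component)
    contigs <- res$contigs
    docs <- res$docs
  } else if (config$algorithm == "SW") {
    contigs <- assemble_sw(graph, min_coverage = config$min_coverage,
                           delta_sw = config$delta_sw,
                           as_printed = config$as_printed,
                           search_budget = config$search_budget)
  } else {
    contigs <- assemble_unitigs(graph, min_coverage = config$min_coverage)
  }
  message(sprintf("%s: %d contigs (%d >= %d bp)", config$algorithm,
                  length(contigs),
                  sum(vapply(contigs, function(ct)
                    nchar(ct$sequence) >= config$min_contig_length,
                    logical(1))),
                  config$min_contig_length))

  summary <- list(algorithm = config$algorithm, k = config$k,
                  nodes = sum(graph$alive),
                  tips_removed = pruned$tips_removed,
                  low_coverage_removed = pruned$low_coverage_removed,
                  contigs = length(contigs),
                  contigs_written = 0L)
  if (!is.null(config$output_prefix)) {
    fasta <- paste0(config$output_prefix, ".contigs.fasta")
    summary$contigs_written <-
      write_contigs_fasta(contigs, fasta, config$min_contig_length)
    if (length(docs)) {
      keep <- vapply(contigs, function(ct)
        nchar(ct$sequence) >= config$min_contig_length, logical(1))
      for (di in which(keep)) {
        if (config$emit_gfa) {
          write_gfa2(docs[[di]], sprintf("%s.contig_%d.gfa",
                                         config$output_prefix, di))
        }
        if (config$emit_fastg) {
          write_fastg(docs[[di]], sprintf("%s.contig_%d.fastg",
                                          config$output_prefix, di))
        }
      }
    }
    manifest <- paste0(config$output_prefix, ".manifest.tsv")
    mf <- data.frame(key = names(summary),
                     value = vapply(summary, as.character, character(1)))
    utils::write.table(mf, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(contigs = contigs, docs = docs, graph = graph,
                 summary = summary))
}
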