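#' Read sequencing reads from FASTA or FASTQ
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file into a data
#' frame of sequence records. The format is detected from the first
#' non-empty character (`>` FASTA, `@` FASTQ) unless given explicitly.
#' FASTQ quality strings are parsed and discarded -- the assembler is
#' coverage-driven, not quality-aware. Sequences are uppercased and every
#' character outside `{A,C,G,T,N}` (including IUPAC ambiguity codes) is
#' mapped to `N`; `N` windows are later excluded from k-mer extraction, so
#' real-world inputs stay usable without a hard rejection.
#'
#' Paired files carry no special meaning: pass both mates and they are
#' read in sequence, pairing information is kept only as provenance.
#'
#' @param path Path to a FASTA/FASTQ file, possibly `.gz`.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @return A data frame with columns `id`, `sequence`, `source`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "GGCC"), f)
#' read_sequences(f)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first <- tryCatch(readLines(con, n = 1L), finally = close(con))
    if (!length(first) || !nzchar(first)) {
      stop("cannot detect format of empty file: ", path)
    }
    c1 <- substr(first, 1L, 1L)
    format <- switch(c1, ">" = "fasta", "@" = "fastq",
                     stop("cannot detect sequence format of ", path,
                          " (first character ", sQuote(c1), ")"))
  }
  if (format == "fastq") validate_fastq(path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("malformed ", format, " in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  ids <- names(set)
  if (any(!nzchar(ids))) stop("record with empty id in ", path)
  if (any(!nzchar(seqs))) stop("record with empty sequence in ", path)
  data.frame(id = unname(ids), sequence = unname(seqs),
             source = rep(path, length(seqs)), stringsAsFactors = FALSE)
}

# Structural validation of 4-line FASTQ before handing the file to the
# parser, so malformed records are reported with their line number.
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed fastq in ", path, ": truncated record near line ",
         length(lines), call. = FALSE)
  }
  for (r in seq_len(length(lines) / 4L)) {
    l <- (r - 1L) * 4L
    if (!startsWith(lines[l + 1L], "@")) {
      stop("malformed fastq in ", path, ": line ", l + 1L,
           " does not start a record with '@'", call. = FALSE)
    }
    if (!startsWith(lines[l + 3L], "+")) {
      stop("malformed fastq in ", path, ": line ", l + 3L,
           " is not a '+' separator", call. = FALSE)
    }
    if (!nzchar(lines[l + 2L])) {
      stop("malformed fastq in ", path, ": empty sequence at line ",
           l + 2L, call. = FALSE)
    }
    if (nchar(lines[l + 2L]) != nchar(lines[l + 4L])) {
      stop("malformed fastq in ", path, ": sequence/quality length ",
           "mismatch at line ", l + 4L, call. = FALSE)
    }
  }
  invisible(TRUE)
}
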