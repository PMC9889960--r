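#' Canonical form of a k-mer
#'
#' The canonical representative of a k-mer is the lexicographically smaller
#' of the k-mer and its reverse complement, so that both strands of a
#' sequence map to the same graph node. k must be odd: an even-length k-mer
#' can equal its own reverse complement, which would make the stored
#' orientation ambiguous.
#'
#' @param text A k-length string over `{A,C,G,T}`.
#' @return A list with `kmer` (canonical text) and `orientation`
#'   (`"forward"` if the input already was canonical, else `"reverse"`).
#' @examples
#' canonical_kmer("ACG")  # forward
#' canonical_kmer("TTT")  # reverse: canonical is AAA
#' @export
canonical_kmer <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  k <- nchar(text)
  if (k %% 2L == 0L) {
    stop("k must be odd (even k admits palindromic k-mers with ambiguous ",
         "orientation); got k = ", k)
  }
  if (grepl("[^ACGT]", text)) {
    stop("k-mer contains characters outside {A,C,G,T}: ", text)
  }
  rc <- revcomp(text)
  if (text <= rc) {
    list(kmer = text, orientation = "forward")
  } else {
    list(kmer = rc, orientation = "reverse")
  }
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k)) {
    stop("k must be a single integer")
  }
  k <- as.integer(k)
  if (k < 3L || k > 191L) stop("k must be between 3 and 191; got ", k)
  if (k %% 2L == 0L) {
    stop("k must be odd (even k admits palindromic canonical k-mers); got ",
         k)
  }
  k
}

# All k-length windows of a sequence with their canonical form and
# orientation, fully vectorised. Windows containing characters outside
# {A,C,G,T} are flagged invalid. Returns a list with character vectors
# `window`, `canonical`, logical `valid`, `forward` (TRUE when the window
# already is canonical). Sequences shorter than k yield zero windows.
# `rc_seq` may supply the precomputed reverse complement of `seq`.
canonical_windows <- function(seq, k, rc_seq = NULL) {
  L <- nchar(seq)
  m <- L - k + 1L
  if (m < 1L) {
    return(list(window = character(0), canonical = character(0),
                valid = logical(0), forward = logical(0)))
  }
  fwd <- substring(seq, 1:m, k:L)
  if (is.null(rc_seq)) rc_seq <- revcomp(seq)
  # reverse complement of window i is window (m - i + 1) of the rc sequence
  rcw <- substring(rc_seq, 1:m, k:L)[m:1]
  valid <- !grepl("[^ACGT]", fwd)
  forward <- fwd <= rcw
  list(window = fwd,
       canonical = ifelse(forward, fwd, rcw),
       valid = valid,
       forward = forward)
}
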