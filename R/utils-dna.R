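#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `{A,C,G,T,N}`.
#'
#' @param x Character vector of DNA sequences (uppercase).
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AACN"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Scalar complement of a single base -- hot-loop helper.
comp_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

# Locale-independent string sort/order (radix = C collation). All node and
# output ordering in the package goes through these so results do not depend
# on the session locale.
sort_c <- function(x, decreasing = FALSE) {
  sort(x, method = "radix", decreasing = decreasing)
}

order_c <- function(...) {
  order(..., method = "radix")
}

#' Sample a random DNA sequence
#'
#' Uniform i.i.d. bases. When `distinct_k` is given, sampling is retried
#' until all canonical k-mers of that length are distinct, so the resulting
#' de Bruijn graph at that k is a simple chain -- convenient for fixtures
#' with a known single-contig answer.
#'
#' @param length Sequence length in bases.
#' @param seed Integer seed; all randomness is local to the call.
#' @param distinct_k Optional odd k; require all canonical k-mers distinct.
#' @param max_tries Retry budget for the distinctness requirement.
#' @return A single character string.
#' @export
random_genome <- function(length, seed, distinct_k = NULL, max_tries = 50L) {
  stopifnot(length >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  for (i in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    if (is.null(distinct_k)) return(s)
    km <- canonical_windows(s, distinct_k)$canonical
    if (!anyDuplicated(km)) return(s)
  }
  stop("could not sample a sequence with all distinct canonical ",
       distinct_k, "-mers in ", max_tries, " tries")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a per-component child seed from a master seed; keeps independent
# fixtures reproducible when one component is added or removed. Result is a
# valid 32-bit integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(index)) %%
               2147483647)
}
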