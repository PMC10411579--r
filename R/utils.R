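#' @useDynLib gapatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse-complement of an ACGTN string (IUPAC codes other than N must have
# been normalized away on read).
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Deterministic sub-seed for a named random substream, so one user seed
# drives every generator without coupling their draws. Kept below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
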