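#' Search for containment of a scaffold within larger scaffolds
#'
#' Looks for a single alignment that contains the full query inside a
#' strictly larger scaffold, on either strand. Candidate placements are
#' seeded with exact k-mers sampled along the query, then verified with a
#' containment alignment (query global, target local) whose identity is
#' matches divided by alignment columns, gap columns included.
#'
#' @param query a single named sequence (length-1 named character vector),
#'   or the id of a scaffold in \code{x}.
#' @param x an \code{\link{assembly}} of candidate containing scaffolds.
#' @param min_identity minimum alignment identity to report.
#' @param seed_k exact seed length.
#' @param seed_stride spacing (bp) of sampled seeds along the query.
#' @return data.frame of hits: query_id, target_id, query_coverage,
#'   identity, strand. Self-hits are excluded.
#' @export
containment_search <- function(query, x, min_identity = 0.99,
                               seed_k = 31L, seed_stride = 500L) {
  if (length(query) == 1L && is.null(names(query)) && query %in% names(x)) {
    qid <- query
    qseq <- unclass(x)[[qid]]
  } else {
    stopifnot(is.character(query), length(query) == 1L, !is.null(names(query)))
    qid <- names(query)
    qseq <- toupper(unname(query))
  }
  qlen <- nchar(qseq)
  targets <- names(x)[nchar(x) > qlen & names(x) != qid]
  hits <- list()
  for (tid in targets) {
    tseq <- unclass(x)[[tid]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qseq else revcomp(qseq)
      diags <- seed_diagonals(q, tseq, seed_k, seed_stride)
      if (length(diags) == 0L) next
      pad <- max(100L, ceiling(0.02 * qlen))
      for (d in cluster_diagonals(diags, tol = pad)) {
        ws <- max(0L, min(d) - pad)
        we <- min(nchar(tseq), max(d) + qlen + pad)
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::DNAString(q),
          subject = Biostrings::DNAString(substr(tseq, ws + 1L, we)),
          type = "global-local",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -3, baseOnly = FALSE),
          gapOpening = 5, gapExtension = 2)
        cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
        identity <- Biostrings::nmatch(aln) / cols
        if (identity >= min_identity) {
          hits[[length(hits) + 1L]] <- data.frame(
            query_id = qid, target_id = tid,
            query_coverage = 1.0,  # full query by construction (global-local)
            identity = identity, strand = strand, stringsAsFactors = FALSE)
          break
        }
      }
      if (length(hits) && hits[[length(hits)]]$target_id == tid) break
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(), target_id = character(),
               query_coverage = numeric(), identity = numeric(),
               strand = character(), stringsAsFactors = FALSE)
}

# Diagonals (target pos - query offset) of exact seed matches for seeds
# sampled every seed_stride bp along the query (ends included).
seed_diagonals <- function(qseq, tseq, seed_k, seed_stride) {
  qlen <- nchar(qseq)
  if (qlen < seed_k) return(integer(0))
  offs <- unique(c(seq(0L, qlen - seed_k, by = seed_stride), qlen - seed_k))
  diags <- integer(0)
  for (o in offs) {
    seed <- substr(qseq, o + 1L, o + seed_k)
    if (grepl("N", seed, fixed = TRUE)) next
    m <- gregexpr(seed, tseq, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    diags <- c(diags, as.integer(m) - 1L - o)
  }
  sort(unique(diags))
}

cluster_diagonals <- function(diags, tol) {
  if (length(diags) == 0L) return(list())
  breaks <- c(0L, which(diff(diags) > tol), length(diags))
  lapply(seq_len(length(breaks) - 1L), function(i)
    diags[(breaks[i] + 1L):breaks[i + 1L]])
}

#' Remove redundant scaffolds
#'
#' Scaffolds shorter than \code{max_len} that align over their full length
#' at identity >= \code{min_identity} within a strictly larger retained
#' scaffold are removed. Queries are processed from smallest to largest and
#' containment is evaluated against retained scaffolds only, so a chain
#' A within B within C (B removed) still tests A against C.
#'
#' @param x an \code{\link{assembly}}.
#' @param max_len only scaffolds strictly shorter than this are candidates
#'   for removal (default 200 kb).
#' @param min_identity identity threshold (default 0.99).
#' @param required_coverage required query coverage (default 1.0).
#' @param seed_k,seed_stride passed to \code{\link{containment_search}}.
#' @return list with \code{assembly} (retained scaffolds, input order) and
#'   \code{removed}, a data.frame (query_id, target_id, query_coverage,
#'   identity, strand).
#' @export
remove_redundant <- function(x, max_len = 200000L, min_identity = 0.99,
                             required_coverage = 1.0,
                             seed_k = 31L, seed_stride = 500L) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            required_coverage >= 0, required_coverage <= 1)
  lens <- nchar(x)
  candidates <- names(x)[lens < max_len]
  candidates <- candidates[order(lens[candidates])]
  retained <- names(x)
  removed <- list()
  for (qid in candidates) {
    pool <- x[setdiff(retained, qid)]
    h <- containment_search(unclass(x)[qid], pool,
                            min_identity = min_identity,
                            seed_k = seed_k, seed_stride = seed_stride)
    h <- h[h$identity >= min_identity & h$query_coverage >= required_coverage, ,
           drop = FALSE]
    if (nrow(h)) {
      retained <- setdiff(retained, qid)
      removed[[length(removed) + 1L]] <- h[1, , drop = FALSE]
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(query_id = character(), target_id = character(),
               query_coverage = numeric(), identity = numeric(),
               strand = character(), stringsAsFactors = FALSE)
  list(assembly = x[names(x) %in% retained], removed = removed)
}
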