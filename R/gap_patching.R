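#' Donor assembly
#'
#' Tags a contig set with the k-mer size of the shotgun assembly it came
#' from. The k-mer size is used only to order donors: when several donors
#' can patch the same gap, the one assembled at the largest k wins.
#'
#' @param x an \code{\link{assembly}} (or named character vector) of contigs.
#' @param kmer_size positive integer label.
#' @return list of class \code{"donor_assembly"}.
#' @export
donor_assembly <- function(x, kmer_size) {
  stopifnot(is.numeric(kmer_size), length(kmer_size) == 1L, kmer_size > 0)
  if (!inherits(x, "assembly")) x <- assembly(x)
  structure(list(assembly = x, kmer_size = as.integer(kmer_size)),
            class = "donor_assembly")
}

# Separator long enough that no alignment within the edit budget can
# straddle two contigs of the concatenated donor text.
.SEP_LEN <- 256L

flank_miss <- function(reason) {
  structure(list(reason = reason), class = "flank_miss")
}

#' Did a flank mapping succeed?
#'
#' @param x a \code{\link{map_flank}} result.
#' @return TRUE for a \code{"flank_hit"}, FALSE for a \code{"flank_miss"}.
#' @export
is_flank_hit <- function(x) inherits(x, "flank_hit")

# One searchable text per donor: contigs joined by X-runs plus a k-mer
# index over it. Built once per donor and reused for every flank.
donor_index <- function(donor, seed_k = 12L) {
  contigs <- unclass(donor$assembly)
  sep <- strrep("X", .SEP_LEN)
  text <- paste(contigs, collapse = sep)
  offsets <- cumsum(c(0L, (nchar(contigs) + .SEP_LEN)[-length(contigs)]))
  idx <- cpp_kmer_index(text, as.integer(seed_k))
  list(text = text, keys = idx$keys, pos = idx$pos, k = idx$k,
       contig_ids = names(contigs), offsets = offsets,
       lengths = nchar(contigs), kmer_size = donor$kmer_size)
}

# Map concatenated-text coordinates back to a contig; NULL if the span is
# not fully inside one contig.
locate_contig <- function(index, start, end) {
  i <- findInterval(start, index$offsets)
  if (i < 1L) return(NULL)
  off <- index$offsets[i]
  if (start < off || end > off + index$lengths[i]) return(NULL)
  list(contig_id = index$contig_ids[i], start = start - off, end = end - off)
}

#' Flank-length schedule for gap patching
#'
#' Flanks of decreasing size are tried for each gap, starting at
#' \code{max_len} and stepping down to \code{min_len}.
#'
#' @param max_len,min_len,step schedule bounds in bp (defaults 1000, 100, 100).
#' @return descending integer vector of flank lengths.
#' @export
flank_schedule <- function(max_len = 1000L, min_len = 100L, step = 100L) {
  if (!(max_len >= min_len && min_len >= step && step > 0))
    stop("require max_len >= min_len >= step > 0")
  as.integer(seq(from = max_len, to = min_len, by = -step))
}

#' Map a flank sequence to a donor assembly
#'
#' Seeded approximate search for a gap flank in a donor contig set, both
#' strands. A hit is accepted only if its edit distance is at most
#' \code{max_edit_fraction} times the flank length AND no second hit at a
#' distinct location comes within \code{ambiguity_margin} edits of the best
#' (the unambiguous-mapping rule).
#'
#' @param flank N-free sequence (character scalar).
#' @param donor a \code{\link{donor_assembly}}.
#' @param max_edit_fraction maximum edit distance as a fraction of length.
#' @param ambiguity_margin a runner-up within this many edits of the best
#'   hit makes the mapping ambiguous.
#' @param index optional prebuilt index from an earlier call (internal reuse).
#' @param seed_k exact seed length for candidate generation.
#' @return list of class \code{"flank_hit"} with contig_id, start, end
#'   (0-based half-open contig coordinates of the matching span), strand,
#'   edit_distance; on failure, a list of class \code{"flank_miss"} with a
#'   \code{reason} element ("no_hit" or "ambiguous").
#' @export
map_flank <- function(flank, donor, max_edit_fraction = 0.10,
                      ambiguity_margin = 1L, index = NULL, seed_k = 12L) {
  stopifnot(is.character(flank), length(flank) == 1L, nchar(flank) >= 1L)
  flank <- toupper(flank)
  if (grepl("N", flank, fixed = TRUE))
    stop("flank contains N; supply N-free flanks")
  if (is.null(index)) index <- donor_index(donor, seed_k)
  m <- nchar(flank)
  max_dist <- floor(max_edit_fraction * m)
  limit <- as.integer(max_dist + ambiguity_margin)
  if (limit + 1L >= .SEP_LEN) stop("flank too long for contig separator")

  # long patterns must be supported by >= 2 exact seeds before the banded
  # DP verifies a candidate; short ones (baits) keep single-seed candidates
  min_support <- if (m >= 300L) 2L else 1L
  fwd <- cpp_seed_search(flank, index$text, index$keys, index$pos,
                         index$k, limit, 16L, min_support)
  rev <- cpp_seed_search(revcomp(flank), index$text, index$keys, index$pos,
                         index$k, limit, 16L, min_support)
  hits <- rbind(
    if (nrow(fwd)) cbind(fwd, strand = 1L),
    if (nrow(rev)) cbind(rev, strand = -1L))
  if (is.null(hits) || nrow(hits) == 0L) return(flank_miss("no_hit"))
  hits <- hits[order(hits[, "dist"], hits[, "start"]), , drop = FALSE]

  # collapse hits at the same physical location (overlap > m/2)
  kept <- matrix(integer(0), 0, 4)
  for (i in seq_len(nrow(hits))) {
    ov <- if (nrow(kept)) pmin(hits[i, "end"], kept[, 2]) -
            pmax(hits[i, "start"], kept[, 1]) else integer(0)
    if (!any(ov > m %/% 2)) kept <- rbind(kept, hits[i, ])
  }
  best <- kept[1, ]
  if (best["dist"] > max_dist) return(flank_miss("no_hit"))
  if (nrow(kept) > 1L && kept[2, "dist"] <= best["dist"] + ambiguity_margin)
    return(flank_miss("ambiguous"))
  loc <- locate_contig(index, best[["start"]], best[["end"]])
  if (is.null(loc)) return(flank_miss("no_hit"))
  structure(list(contig_id = loc$contig_id,
                 start = unname(loc$start), end = unname(loc$end),
                 strand = if (best[["strand"]] > 0) "+" else "-",
                 edit_distance = unname(as.integer(best[["dist"]]))),
            class = "flank_hit")
}

# Try to patch one gap (current coordinates g_start/g_end in seq) against a
# set of donor indices. Returns a list describing the outcome.
try_patch_gap <- function(seq, g_start, g_end, indices, schedule,
                          max_insert, max_edit_fraction, ambiguity_margin) {
  L <- nchar(seq)
  reason <- "no_flank"
  for (fl in schedule) {
    ls <- g_start - fl
    re <- g_end + fl
    if (ls < 0L || re > L) next
    left <- substr(seq, ls + 1L, g_start)
    right <- substr(seq, g_end + 1L, re)
    if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE))
      next
    for (idx in indices) {
      lh <- map_flank(left, donor = NULL, max_edit_fraction = max_edit_fraction,
                      ambiguity_margin = ambiguity_margin, index = idx)
      rh <- map_flank(right, donor = NULL, max_edit_fraction = max_edit_fraction,
                      ambiguity_margin = ambiguity_margin, index = idx)
      if (!is_flank_hit(lh) || !is_flank_hit(rh)) {
        reason <- if (!is_flank_hit(lh)) lh$reason else rh$reason
        next
      }
      if (lh$contig_id != rh$contig_id) { reason <- "different_contig"; next }
      if (lh$strand != rh$strand) { reason <- "wrong_orientation"; next }
      if (lh$strand == "+") {
        if (rh$end <= lh$start) { reason <- "wrong_orientation"; next }
        inner <- rh$start - lh$end
        span <- c(lh$start, rh$end)
      } else {
        if (lh$end <= rh$start) { reason <- "wrong_orientation"; next }
        inner <- lh$start - rh$end
        span <- c(rh$start, lh$end)
      }
      if (inner < 0L) { reason <- "overlap"; next }
      if (inner > max_insert) { reason <- "too_long"; next }
      ci <- match(lh$contig_id, idx$contig_ids)
      off <- idx$offsets[ci]
      patch_seq <- substr(idx$text, off + span[1] + 1L, off + span[2])
      if (lh$strand == "-") patch_seq <- revcomp(patch_seq)
      if (grepl("N", patch_seq, fixed = TRUE)) { reason <- "donor_gap"; next }
      return(list(status = "patched", donor_kmer = idx$kmer_size,
                  donor_contig = lh$contig_id, flank_length_used = fl,
                  inserted_length = inner,
                  replaced_start = ls, replaced_end = re,
                  patch_seq = patch_seq))
    }
  }
  list(status = "unpatched", reason = reason)
}

#' Patch assembly gaps from donor assemblies
#'
#' For each N-run gap, flanks of decreasing length (per \code{schedule}) are
#' extracted immediately adjacent to the gap and mapped to each donor in
#' descending k-mer-size order. A gap is patched when both flanks map
#' unambiguously to the same donor contig, on the same strand, in the
#' correct order: the scaffold region from the start of the left flank to
#' the end of the right flank is then replaced by the donor span between the
#' outermost mapping coordinates (reverse-complemented for minus-strand
#' hits). Flank windows that run off the scaffold or touch another gap fall
#' through to the next (shorter) flank length.
#'
#' @param x an \code{\link{assembly}} with gaps.
#' @param donors list of \code{\link{donor_assembly}} objects.
#' @param schedule descending flank lengths, see \code{\link{flank_schedule}}.
#' @param max_insert sanity cap (bp) on the inserted inner sequence.
#' @param min_run minimum N-run length treated as a gap.
#' @param max_edit_fraction,ambiguity_margin passed to \code{\link{map_flank}}.
#' @param seed_k exact seed length for the donor search index.
#' @return list with \code{assembly} (patched) and \code{patches}, a
#'   data.frame with one row per gap: scaffold_id, gap coordinates (on the
#'   input assembly), status ("patched"/"unpatched"), reason for unpatched
#'   gaps (no_hit, ambiguous, different_contig, wrong_orientation, overlap,
#'   too_long, donor_gap, no_flank), donor kmer/contig, flank length,
#'   inserted length and the replaced span.
#' @export
patch_gaps <- function(x, donors, schedule = flank_schedule(),
                       max_insert = 50000L, min_run = 1L,
                       max_edit_fraction = 0.10, ambiguity_margin = 1L,
                       seed_k = 12L) {
  if (length(donors) == 0L) stop("at least one donor assembly is required")
  if (inherits(donors, "donor_assembly")) donors <- list(donors)
  if (is.unsorted(rev(schedule), strictly = TRUE) && length(schedule) > 1L)
    stop("schedule must be strictly descending")
  ks <- vapply(donors, function(d) d$kmer_size, integer(1))
  indices <- lapply(donors[order(ks, decreasing = TRUE)], donor_index,
                    seed_k = seed_k)

  out_seqs <- unclass(x)
  records <- list()
  for (sid in names(out_seqs)) {
    seq <- out_seqs[[sid]]
    gaps <- find_gaps(stats::setNames(seq, sid), min_run)
    delta <- 0L
    for (gi in seq_len(nrow(gaps))) {
      g0 <- gaps$start[gi]
      g1 <- gaps$end[gi]
      res <- try_patch_gap(seq, g0 + delta, g1 + delta, indices, schedule,
                           max_insert, max_edit_fraction, ambiguity_margin)
      rec <- data.frame(scaffold_id = sid, gap_start = g0, gap_end = g1,
                        status = res$status,
                        reason = res$reason %||% NA_character_,
                        donor_kmer = res$donor_kmer %||% NA_integer_,
                        donor_contig = res$donor_contig %||% NA_character_,
                        flank_length_used = res$flank_length_used %||% NA_integer_,
                        inserted_length = res$inserted_length %||% NA_integer_,
                        replaced_start = if (is.null(res$replaced_start))
                          NA_integer_ else res$replaced_start - delta,
                        replaced_end = if (is.null(res$replaced_end))
                          NA_integer_ else res$replaced_end - delta,
                        stringsAsFactors = FALSE)
      records[[length(records) + 1L]] <- rec
      if (res$status == "patched") {
        rs <- res$replaced_start   # current coordinates
        re <- res$replaced_end
        seq <- paste0(substr(seq, 1L, rs), res$patch_seq,
                      substr(seq, re + 1L, nchar(seq)))
        delta <- delta + nchar(res$patch_seq) - (re - rs)
      }
    }
    out_seqs[[sid]] <- seq
  }
  patches <- if (length(records)) do.call(rbind, records) else
    data.frame(scaffold_id = character(), gap_start = integer(),
               gap_end = integer(), status = character(),
               reason = character(), donor_kmer = integer(),
               donor_contig = character(), flank_length_used = integer(),
               inserted_length = integer(), replaced_start = integer(),
               replaced_end = integer(), stringsAsFactors = FALSE)
  list(assembly = assembly(out_seqs), patches = patches)
}

#' Count gaps closed between two assembly versions
#'
#' @param before,after assemblies with identical scaffold id sets.
#' @param min_run minimum N-run length treated as a gap.
#' @return integer: gaps(before) - gaps(after).
#' @export
count_filled <- function(before, after, min_run = 1L) {
  if (!setequal(names(before), names(after)))
    stop("scaffold ids differ between assemblies")
  nrow(find_gaps(before, min_run)) - nrow(find_gaps(after, min_run))
}
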