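#' Extract UCE loci from an assembly around capture baits
#'
#' Each bait (~120 bp probe) is mapped to the assembly on both strands with
#' the seeded edit-distance search. Baits with a unique best hit at identity
#' >= \code{min_identity} yield a slice of \code{slice_length} bp centered
#' on the hit midpoint, reverse-complemented to bait orientation for
#' minus-strand hits and clamped (and flagged) at scaffold ends. Baits whose
#' best hit is ambiguous (a second location at least as close within
#' \code{ambiguity_margin} edits) or absent are skipped with a reason.
#' When several baits resolve to the same locus the lowest-edit-distance
#' slice is kept.
#'
#' @param x an \code{\link{assembly}}.
#' @param baits named character vector of N-free bait sequences; the locus
#'   id is the bait id with any trailing probe suffix (e.g. "_p1") removed.
#' @param slice_length slice size in bp (default 2500).
#' @param min_identity minimum hit identity, as 1 - edits/length (default 0.8).
#' @param ambiguity_margin runner-up margin in edits (default 0: a tie is
#'   ambiguous, a strictly worse runner-up is not).
#' @param seed_k exact seed length for candidate generation.
#' @return list with \code{loci} (named character vector, one slice per
#'   locus) and \code{report} (per-bait data.frame with placement, status
#'   and clamped flag).
#' @export
extract_uce_loci <- function(x, baits, slice_length = 2500L,
                             min_identity = 0.8, ambiguity_margin = 0L,
                             seed_k = 12L) {
  stopifnot(length(baits) > 0L, !is.null(names(baits)))
  if (any(grepl("N", baits))) stop("bait sequences must be N-free")
  donor <- donor_assembly(x, kmer_size = 1L)   # index container only
  idx <- donor_index(donor, seed_k)
  rows <- list()
  for (bid in names(baits)) {
    bait <- toupper(baits[[bid]])
    hit <- map_flank(bait, donor = NULL,
                     max_edit_fraction = 1 - min_identity,
                     ambiguity_margin = ambiguity_margin, index = idx)
    locus <- sub("_[Pp]?\\d+$", "", bid)
    if (!is_flank_hit(hit)) {
      rows[[bid]] <- data.frame(
        bait_id = bid, locus_id = locus, scaffold = NA_character_,
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        edit_distance = NA_integer_, status = hit$reason,
        clamped = NA, stringsAsFactors = FALSE)
      next
    }
    slen <- nchar(unclass(x)[[hit$contig_id]])
    mid <- (hit$start + hit$end) %/% 2L
    s0 <- mid - slice_length %/% 2L
    s1 <- s0 + slice_length
    clamped <- s0 < 0L || s1 > slen
    s0 <- max(0L, s0); s1 <- min(slen, s1)
    slice <- substr(unclass(x)[[hit$contig_id]], s0 + 1L, s1)
    if (hit$strand == "-") slice <- revcomp(slice)
    rows[[bid]] <- data.frame(
      bait_id = bid, locus_id = locus, scaffold = hit$contig_id,
      start = s0, end = s1, strand = hit$strand,
      edit_distance = hit$edit_distance, status = "extracted",
      clamped = clamped, stringsAsFactors = FALSE)
    attr(rows[[bid]], "slice") <- slice
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  ok <- which(report$status == "extracted")
  loci <- character(0)
  if (length(ok)) {
    ord <- ok[order(report$locus_id[ok], report$edit_distance[ok])]
    ord <- ord[!duplicated(report$locus_id[ord])]
    loci <- vapply(ord, function(i) attr(rows[[report$bait_id[i]]], "slice"),
                   character(1))
    names(loci) <- report$locus_id[ord]
  }
  list(loci = loci, report = report)
}

# Majority-rule consensus of a reference locus alignment (named character
# vector of equal-length aligned sequences). Per column: most frequent base
# among A/C/G/T (gaps and N ignored), ties to the alphabetically first;
# all-gap/N columns become N. The result has no gaps.
consensus_majority <- function(reference) {
  stopifnot(length(reference) >= 2L)
  L <- unique(nchar(reference))
  if (length(L) != 1L) stop("reference alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(reference), ""))
  cons <- apply(m, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return("N")
    tab <- table(col)
    names(tab)[which.max(tab)]   # which.max ties -> first name, alphabetical
  })
  paste(cons, collapse = "")
}

#' Trim a sample sequence to a reference locus alignment
#'
#' Globally aligns the reference alignment's majority-rule consensus into
#' the sample sequence (consensus global, sample local), then projects the
#' sample into the alignment columns: each consensus column receives the
#' sample base aligned to it, "-" where the sample has a deletion, and
#' sample insertions are discarded. Overhanging sample sequence is dropped;
#' reference columns not covered by the sample come back as missing.
#'
#' @param sample_seq unaligned sample sequence (character scalar).
#' @param reference named character vector: the reference locus alignment
#'   (>= 2 equal-length rows over A/C/G/T/N/-).
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2; the gap
#'   penalty is linear).
#' @param min_score score floor; an alignment scoring below it rejects the
#'   locus for this sample (default: a quarter of the alignment length).
#' @return character scalar of exactly the alignment length, or a list of
#'   class \code{"locus_reject"} (reason "low_score") when rejected.
#' @export
trim_to_reference <- function(sample_seq, reference, match = 1,
                              mismatch = -1, gap = -2, min_score = NULL) {
  cons <- consensus_majority(reference)
  L <- nchar(cons)
  if (is.null(min_score)) min_score <- 0.25 * L
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(cons),
    subject = Biostrings::DNAString(toupper(sample_seq)),
    type = "overlap", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = -gap)
  if (Biostrings::score(aln) < min_score)
    return(structure(list(reason = "low_score"), class = "locus_reject"))
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- rep("-", L)   # consensus columns outside the aligned range: missing
  col <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  for (i in seq_along(pa)) {
    if (pa[i] != "-") {
      col <- col + 1L
      out[col] <- if (sa[i] == "-") "-" else sa[i]
    }
  }
  paste(out, collapse = "")
}

#' Build a genotype matrix from per-locus alignments
#'
#' Scans every alignment column of every locus; sites that are biallelic
#' among non-missing calls (N and "-" are missing) are retained, coded 0
#' for the major allele (frequency ties broken alphabetically) and 1 for
#' the minor. Site order is lexicographic in (locus_id, column). Haploid
#' coding reflects the zero within-locus heterozygosity of the system;
#' diploid 0/1/2 matrices can be passed to \code{\link{snmf_ancestry}}
#' directly.
#'
#' @param alignments named list: locus_id -> named character vector of
#'   equal-length sequences (samples may differ between loci).
#' @param pop_labels optional named character vector: sample -> population.
#' @return integer matrix (samples x sites, NA = missing) of class
#'   \code{"genotype_matrix"} with attributes \code{sites} (data.frame:
#'   locus_id, column, allele0, allele1) and optional \code{pop}.
#' @export
build_genotype_matrix <- function(alignments, pop_labels = NULL) {
  stopifnot(length(alignments) > 0L, !is.null(names(alignments)))
  samples <- sort(unique(unlist(lapply(alignments, names))))
  if (length(samples) < 2L) stop("need at least 2 samples")
  loci <- sort(names(alignments))
  calls <- list()
  sites <- list()
  for (locus in loci) {
    aln <- toupper(alignments[[locus]])
    L <- unique(nchar(aln))
    if (length(L) != 1L) stop("locus ", locus, ": rows differ in length")
    m <- do.call(rbind, strsplit(aln, ""))
    rownames(m) <- names(aln)
    for (j in seq_len(L)) {
      col <- m[, j]
      col[!col %in% c("A", "C", "G", "T")] <- NA
      alleles <- sort(unique(col[!is.na(col)]))
      if (length(alleles) != 2L) next
      n0 <- sum(col == alleles[1], na.rm = TRUE)
      n1 <- sum(col == alleles[2], na.rm = TRUE)
      major <- if (n1 > n0) alleles[2] else alleles[1]  # tie -> alphabetical
      minor <- setdiff(alleles, major)
      v <- rep(NA_integer_, length(samples))
      names(v) <- samples
      v[names(col)] <- ifelse(is.na(col), NA_integer_,
                              ifelse(col == major, 0L, 1L))
      calls[[length(calls) + 1L]] <- v
      sites[[length(sites) + 1L]] <- data.frame(
        locus_id = locus, column = j, allele0 = major, allele1 = minor,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L)
    stop("no biallelic sites with at least 2 non-missing calls")
  gm <- do.call(cbind, calls)
  rownames(gm) <- samples
  structure(gm, sites = do.call(rbind, sites),
            pop = pop_labels, class = c("genotype_matrix", class(gm)))
}

#' Rank loci by population diagnosticity
#'
#' Scores each locus by the mean absolute allele-frequency differential of
#' its sites between two labeled populations; loci fixed for alternate
#' alleles score 1.0. Ties are broken by locus_id. Loci at which one
#' population has no non-missing calls are left unranked with a warning.
#'
#' @param gm a \code{\link{build_genotype_matrix}} result.
#' @param pop_labels named character vector sample -> population (two
#'   populations); defaults to the matrix's \code{pop} attribute. Samples
#'   without a label (e.g. the focal specimen) are ignored for ranking.
#' @param top_n optionally return only the best \code{top_n} loci.
#' @return data.frame (locus_id, n_sites, differential), descending.
#' @export
rank_diagnostic_loci <- function(gm, pop_labels = attr(gm, "pop"),
                                 top_n = NULL) {
  if (is.null(pop_labels)) stop("population labels required")
  pop_labels <- pop_labels[names(pop_labels) %in% rownames(gm)]
  pops <- sort(unique(pop_labels))
  if (length(pops) != 2L) stop("exactly two populations required")
  sites <- attr(gm, "sites")
  s1 <- names(pop_labels)[pop_labels == pops[1]]
  s2 <- names(pop_labels)[pop_labels == pops[2]]
  out <- lapply(unique(sites$locus_id), function(locus) {
    cols <- which(sites$locus_id == locus)
    p1 <- colMeans(gm[s1, cols, drop = FALSE], na.rm = TRUE)
    p2 <- colMeans(gm[s2, cols, drop = FALSE], na.rm = TRUE)
    if (all(is.nan(p1)) || all(is.nan(p2))) {
      warning("locus ", locus, " unranked: a population has no calls")
      return(NULL)
    }
    d <- abs(p1 - p2)
    data.frame(locus_id = locus, n_sites = length(cols),
               differential = mean(d, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$differential, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Subset a genotype matrix to a set of loci
#'
#' @param gm a \code{\link{build_genotype_matrix}} result.
#' @param loci locus ids to keep.
#' @return genotype matrix restricted to those loci's sites.
#' @export
subset_loci <- function(gm, loci) {
  sites <- attr(gm, "sites")
  keep <- which(sites$locus_id %in% loci)
  structure(gm[, keep, drop = FALSE], sites = sites[keep, , drop = FALSE],
            pop = attr(gm, "pop"), class = class(gm))
}
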