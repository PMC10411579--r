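#' Simulate a genome with a given GC content
#'
#' I.i.d. bases with P(G) + P(C) = \code{gc}. The default GC of 0.405
#' matches the focal snake assembly's composition.
#'
#' @param length total genome length in bp.
#' @param gc GC fraction in (0, 1) (endpoints allowed for degenerate tests).
#' @param seed RNG seed.
#' @param n_scaffolds split the genome into this many equal-ish scaffolds.
#' @return an \code{\link{assembly}}.
#' @export
simulate_genome <- function(length, gc = 0.405, seed = 1L, n_scaffolds = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1, n_scaffolds >= 1L)
  set.seed(derive_seed(seed, "genome"))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  cuts <- floor(seq(0, length, length.out = n_scaffolds + 1L))
  seqs <- vapply(seq_len(n_scaffolds), function(i)
    paste(bases[(cuts[i] + 1L):cuts[i + 1L]], collapse = ""), character(1))
  names(seqs) <- sprintf("scaffold%02d", seq_len(n_scaffolds))
  assembly(seqs)
}

#' Replace spans of a truth genome with N-run gaps
#'
#' Places \code{n_gaps} non-overlapping N-runs, at least
#' \code{min_separation} bp apart and \code{edge_margin} bp from scaffold
#' ends (so full-length flanks stay clean), recording each gap's hidden
#' sequence. Restoring every hidden sequence reconstructs the truth exactly.
#' Gaps are allocated to scaffolds proportionally to length.
#'
#' @param truth an \code{\link{assembly}} without gaps.
#' @param n_gaps number of gaps to create.
#' @param gap_len_range integer range of gap lengths (default 500-2000 bp).
#' @param min_separation minimum distance between gaps (default 2000 bp).
#' @param edge_margin minimum distance from scaffold ends (default 1500 bp).
#' @param seed RNG seed.
#' @return list of class \code{"gap_sim"}: truth, gapped (assembly), gaps
#'   (data.frame: scaffold_id, start, end, length, hidden, coverable), seed.
#' @export
introduce_gaps <- function(truth, n_gaps, gap_len_range = c(500L, 2000L),
                           min_separation = 2000L, edge_margin = 1500L,
                           seed = 1L) {
  stopifnot(n_gaps >= 1L)
  set.seed(derive_seed(seed, "gaps"))
  lens <- nchar(truth)
  alloc <- diff(round(cumsum(c(0, lens / sum(lens))) * n_gaps))
  names(alloc) <- names(truth)
  gapped <- unclass(truth)
  recs <- list()
  for (sid in names(truth)) {
    ng <- alloc[[sid]]
    if (ng == 0L) next
    L <- lens[[sid]]
    glen <- sample(gap_len_range[1]:gap_len_range[2], ng, replace = TRUE)
    needed <- sum(glen) + (ng - 1L) * min_separation + 2L * edge_margin
    if (needed > L)
      stop("cannot place ", ng, " gaps in scaffold ", sid,
           ": need ", needed, " bp, have ", L)
    slack <- L - needed
    extra <- sort(stats::runif(ng, 0, slack))
    starts <- as.integer(edge_margin + extra +
                           cumsum(c(0, glen[-ng] + min_separation)))
    ends <- starts + glen
    hidden <- substring(gapped[[sid]], starts + 1L, ends)
    for (i in seq_len(ng))
      substr(gapped[[sid]], starts[i] + 1L, ends[i]) <-
        strrep("N", glen[i])
    recs[[sid]] <- data.frame(scaffold_id = sid, start = starts, end = ends,
                              length = glen, hidden = hidden,
                              coverable = TRUE, stringsAsFactors = FALSE)
  }
  gaps <- do.call(rbind, recs)
  rownames(gaps) <- NULL
  structure(list(truth = truth, gapped = assembly(gapped), gaps = gaps,
                 seed = seed), class = "gap_sim")
}

#' Build donor shotgun assemblies from a truth genome
#'
#' For each k-mer size label, the truth is tiled into contigs of
#' \code{contig_len} bp with a random phase. A random subset of gaps
#' (fraction \code{1 - cover_fraction}) is made unpatchable: its hidden
#' spans are excised from every donor, so contigs never carry or cross
#' those spans, and the gaps are flagged \code{coverable = FALSE}.
#' Substitution errors are applied i.i.d. at \code{error_rate}.
#'
#' @param sim a \code{\link{introduce_gaps}} result.
#' @param k_list k-mer size labels (defaults to the shotgun-assembly sweep
#'   37, 47, ..., 117).
#' @param contig_len donor contig length in bp.
#' @param error_rate per-base substitution probability (< 0.05).
#' @param cover_fraction fraction of gaps left coverable.
#' @param min_contig drop donor pieces shorter than this.
#' @param seed RNG seed.
#' @return the \code{gap_sim} with updated \code{gaps$coverable} and a
#'   \code{donors} element (list of \code{\link{donor_assembly}}).
#' @export
make_donors <- function(sim, k_list = seq(37L, 117L, by = 10L),
                        contig_len = 10000L, error_rate = 0,
                        cover_fraction = 1, min_contig = 200L, seed = 1L) {
  stopifnot(inherits(sim, "gap_sim"), error_rate >= 0, error_rate < 0.05,
            cover_fraction >= 0, cover_fraction <= 1)
  set.seed(derive_seed(seed, "donors"))
  n_gaps <- nrow(sim$gaps)
  n_uncov <- round((1 - cover_fraction) * n_gaps)
  uncov <- if (n_uncov > 0) sample(n_gaps, n_uncov) else integer(0)
  sim$gaps$coverable <- !seq_len(n_gaps) %in% uncov

  # per-scaffold keep-intervals: truth minus the uncoverable hidden spans
  keep <- lapply(names(sim$truth), function(sid) {
    L <- nchar(sim$truth[[sid]])
    g <- sim$gaps[sim$gaps$scaffold_id == sid & !sim$gaps$coverable, ,
                  drop = FALSE]
    bounds <- c(0L, rbind(g$start, g$end), L)
    m <- matrix(bounds, ncol = 2, byrow = TRUE)
    m[m[, 2] > m[, 1], , drop = FALSE]
  })
  names(keep) <- names(sim$truth)

  donors <- lapply(k_list, function(k) {
    set.seed(derive_seed(seed, paste0("donor_k", k)))
    phase <- sample.int(contig_len, 1L) - 1L
    contigs <- character(0)
    for (sid in names(sim$truth)) {
      for (r in seq_len(nrow(keep[[sid]]))) {
        a <- keep[[sid]][r, 1]; b <- keep[[sid]][r, 2]
        first <- a + ((phase - a) %% contig_len)
        grid <- if (first < b) seq.int(first, b - 1L, by = contig_len)
                else integer(0)
        cuts <- sort(unique(c(a, grid[grid > a], b)))
        for (j in seq_len(length(cuts) - 1L)) {
          piece <- substr(sim$truth[[sid]], cuts[j] + 1L, cuts[j + 1L])
          if (nchar(piece) >= min_contig)
            contigs <- c(contigs, piece)
        }
      }
    }
    if (error_rate > 0) contigs <- vapply(contigs, mutate_seq,
                                          character(1), rate = error_rate,
                                          USE.NAMES = FALSE)
    names(contigs) <- sprintf("k%d_c%05d", k, seq_along(contigs))
    donor_assembly(assembly(contigs), kmer_size = k)
  })
  sim$donors <- donors
  sim
}

# i.i.d. substitutions at the given per-base rate (always to a different base)
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (length(pos) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

#' Simulate two diverged populations at many loci
#'
#' Each locus descends from a random ancestral sequence; at
#' \code{fixed_diffs_per_locus} sites the two populations are fixed for
#' alternate alleles (allele-frequency differential 1.0). Within-population
#' polymorphism is added at \code{polymorphism_rate} per site per
#' population, as a derived allele segregating at a random frequency.
#' All individuals are haploid at every locus (a single haplotype, no
#' heterozygosity encoding), matching the zero within-locus heterozygosity
#' observed in the system.
#'
#' @param n_per_pop individuals per population (default 68, i.e. a
#'   136-individual two-species panel).
#' @param n_loci number of loci (default 20, the diagnostic panel size).
#' @param locus_len locus length in bp.
#' @param fixed_diffs_per_locus fixed differences per locus; a scalar, or a
#'   vector of length \code{n_loci} (0 makes a locus non-diagnostic).
#' @param polymorphism_rate per-site within-population polymorphism rate.
#' @param gc GC content of the ancestral sequences.
#' @param seed RNG seed.
#' @return list of class \code{"pop_sim"}: loci (named list locus_id ->
#'   named character vector of individual haplotypes), labels (named
#'   vector sample -> "pop1"/"pop2"), diag (data.frame locus_id,
#'   n_fixed_diffs), seed.
#' @export
simulate_populations <- function(n_per_pop = 68L, n_loci = 20L,
                                 locus_len = 600L,
                                 fixed_diffs_per_locus = 2L,
                                 polymorphism_rate = 0.002, gc = 0.4,
                                 seed = 1L) {
  stopifnot(all(fixed_diffs_per_locus >= 0L),
            all(locus_len > fixed_diffs_per_locus))
  fixed_diffs_per_locus <- rep_len(fixed_diffs_per_locus, n_loci)
  set.seed(derive_seed(seed, "populations"))
  samples1 <- sprintf("pop1_%03d", seq_len(n_per_pop))
  samples2 <- sprintf("pop2_%03d", seq_len(n_per_pop))
  loci <- list()
  diag <- list()
  for (l in seq_len(n_loci)) {
    lid <- sprintf("uce-%04d", l)
    anc <- sample(c("A", "C", "G", "T"), locus_len, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    seq1 <- anc
    seq2 <- anc
    fd <- if (fixed_diffs_per_locus[l] > 0)
      sample(locus_len, fixed_diffs_per_locus[l]) else integer(0)
    for (p in fd) {
      alt <- setdiff(c("A", "C", "G", "T"), anc[p])
      seq2[p] <- alt[sample.int(3L, 1L)]
    }
    h1 <- matrix(rep(seq1, n_per_pop), nrow = n_per_pop, byrow = TRUE)
    h2 <- matrix(rep(seq2, n_per_pop), nrow = n_per_pop, byrow = TRUE)
    for (pop in 1:2) {
      h <- if (pop == 1) h1 else h2
      poly <- which(stats::runif(locus_len) < polymorphism_rate)
      poly <- setdiff(poly, fd)
      for (p in poly) {
        ref <- h[1, p]
        alt <- setdiff(c("A", "C", "G", "T"), ref)[sample.int(3L, 1L)]
        freq <- stats::runif(1, 0.1, 0.5)
        carriers <- which(stats::runif(n_per_pop) < freq)
        h[carriers, p] <- alt
      }
      if (pop == 1) h1 <- h else h2 <- h
    }
    seqs <- c(apply(h1, 1, paste, collapse = ""),
              apply(h2, 1, paste, collapse = ""))
    names(seqs) <- c(samples1, samples2)
    loci[[lid]] <- seqs
    diag[[lid]] <- data.frame(locus_id = lid,
                              n_fixed_diffs = fixed_diffs_per_locus[l],
                              stringsAsFactors = FALSE)
  }
  labels <- stats::setNames(rep(c("pop1", "pop2"), each = n_per_pop),
                            c(samples1, samples2))
  structure(list(loci = loci, labels = labels,
                 diag = do.call(rbind, diag), seed = seed),
            class = "pop_sim")
}

#' Simulate admixed individuals from parental panels
#'
#' For each individual and locus, the haplotype is copied from a random
#' population-1 parental with probability \code{q}, otherwise from a random
#' population-2 parental. Individuals carry a single haplotype per locus
#' (no heterozygosity), and both the nominal and the realized (per-locus
#' draw) ancestry fractions are recorded.
#'
#' @param parentals a \code{\link{simulate_populations}} result.
#' @param q population-1 ancestry fraction (default 0.59, the focal
#'   specimen's estimated coefficient).
#' @param n_individuals number of admixed individuals.
#' @param seed RNG seed.
#' @param prefix sample-id prefix.
#' @return the \code{pop_sim} with the hybrids added to every locus
#'   (unlabeled) and a \code{hybrids} data.frame (sample, q_true,
#'   q_realized).
#' @export
simulate_admixed <- function(parentals, q = 0.59, n_individuals = 1L,
                             seed = 1L, prefix = "hyb") {
  stopifnot(inherits(parentals, "pop_sim"), q >= 0, q <= 1)
  set.seed(derive_seed(seed, "admixed"))
  ids <- sprintf("%s_%03d", prefix, seq_len(n_individuals))
  p1 <- names(parentals$labels)[parentals$labels == "pop1"]
  p2 <- names(parentals$labels)[parentals$labels == "pop2"]
  from_p1 <- matrix(stats::runif(n_individuals * length(parentals$loci)) < q,
                    nrow = n_individuals)
  for (l in seq_along(parentals$loci)) {
    lid <- names(parentals$loci)[l]
    new <- vapply(seq_len(n_individuals), function(i) {
      src <- if (from_p1[i, l]) sample(p1, 1L) else sample(p2, 1L)
      parentals$loci[[lid]][[src]]
    }, character(1))
    names(new) <- ids
    parentals$loci[[lid]] <- c(parentals$loci[[lid]], new)
  }
  parentals$hybrids <- data.frame(sample = ids, q_true = q,
                                  q_realized = rowMeans(from_p1),
                                  stringsAsFactors = FALSE)
  parentals
}

#' Simulate a genotype matrix under Dirichlet admixture
#'
#' Sites are fixed differences between K ancestral clusters; each sample's
#' ancestry vector is drawn from a flat Dirichlet, and haploid alleles are
#' drawn independently per site with P(allele 1) = Q G. Used for direct
#' parameter-recovery checks of \code{\link{snmf_ancestry}}.
#'
#' @param n samples.
#' @param n_sites fixed-difference sites.
#' @param K ancestral clusters.
#' @param seed RNG seed.
#' @return list: X (n x n_sites 0/1 matrix), Q_truth (n x K), G_truth
#'   (K x n_sites allele-1 frequencies).
#' @export
simulate_admixture_genotypes <- function(n = 50L, n_sites = 100L, K = 2L,
                                         seed = 1L) {
  set.seed(derive_seed(seed, "dirichlet_genotypes"))
  Q <- matrix(stats::rgamma(n * K, shape = 1), n, K)
  Q <- Q / rowSums(Q)
  G <- matrix(0, K, n_sites)
  for (s in seq_len(n_sites)) {
    carriers <- sample.int(K, sample.int(K - 1L, 1L))
    G[carriers, s] <- 1
  }
  P <- Q %*% G
  X <- matrix(as.integer(stats::runif(n * n_sites) < P), n, n_sites)
  rownames(X) <- sprintf("ind%03d", seq_len(n))
  list(X = X, Q_truth = Q, G_truth = G)
}
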