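---
title: "Finishing a draft genome and screening its specimen for admixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing a draft genome and screening its specimen for admixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapatch)
```

## The problem

Linked-read (10X Chromium) assemblies of large vertebrate genomes arrive as
scaffolds riddled with N-run gaps, often alongside independent shotgun
assemblies of the same reads built at several k-mer sizes. `gapatch`
implements the bespoke computational stages that turn such material into a
finished, quality-screened draft and that screen the sequenced specimen for
interspecific admixture:

1. **Gap patching** — anchor each gap's flanks in a donor shotgun assembly
   and splice in the donor sequence between them.
2. **Redundancy removal** — drop small scaffolds that are near-identical
   copies contained in larger ones.
3. **Assembly statistics** — N50/L50, GC, gap accounting, contig splitting.
4. **Annotation QC** — keep predicted transcripts whose proteins have
   functional-annotation support.
5. **Admixture screening** — extract UCE loci around capture baits, build a
   diagnostic-locus genotype matrix, and estimate ancestry coefficients by
   least-squares sparse nonnegative matrix factorization (sNMF).

A seeded simulator generates every input with known truth, so the whole
pipeline is testable end to end without any downloads.

## Gap patching

For each N-run gap (coordinates are 0-based half-open throughout; GTF/BED
conversion happens only at the file boundary), flanks of decreasing length —
1000 bp down to 100 bp in steps of 100 by default — are taken immediately
adjacent to the gap. A flank window that would run off the scaffold or touch
another gap falls through to the next shorter length, since flanks must be
N-free to anchor unambiguously.

Each flank is searched in the donor contigs on both strands with a seeded
edit-distance scan: exact 12-mer seeds tiled along the flank propose
candidate diagonals, which a banded semi-global dynamic program then scores
exactly. A mapping is accepted only if

* its edit distance is at most 10% of the flank length (`max_edit_fraction`),
  and
* no second hit at a distinct location comes within `ambiguity_margin`
  (default 1) edits of the best — the "unambiguous" rule. Two locations are
  distinct when their spans overlap by at most half the flank length.

A gap is patched when both flanks map unambiguously to the *same* donor
contig, on the *same* strand, in the correct order; the scaffold region from
the left flank's start to the right flank's end is replaced by the donor
span between the outermost mapping coordinates, reverse-complemented for
minus-strand anchors. Donors are tried in descending k-mer size, so
conflicting patches resolve in favor of the assembly built at the largest k
(larger-k contigs resolve repeats better). Unpatched gaps carry a reason
code: `no_hit`, `ambiguous`, `different_contig`, `wrong_orientation`,
`overlap` (flank hits imply a negative insert; closing a gap to zero bases
is allowed only when the anchors abut exactly), `too_long` (inner span above
`max_insert`, default 50 kb — a sanity cap against misjoins from spurious
anchors), `donor_gap` (the donor span itself contains N), or `no_flank`
(no usable N-free window at any scheduled length).

Two numerical caveats are worth knowing. First, seeding bounds sensitivity:
a true hit is only found if at least one 12-mer of the flank survives
unmutated at the hit (and, for flanks of 300 bp or more, two seeds on
consistent diagonals are required before the DP runs). Divergence near the
10% ceiling can therefore be missed; the donors this stage targets are
low-error assemblies of the same individual, where this bound is immaterial.
Second, donor contigs are concatenated with long X runs for indexing; an
alignment can never cross a junction within the edit budget, and hits are
mapped back to contig coordinates.

```{r patch-demo}
sim <- introduce_gaps(simulate_genome(100000, seed = 21), n_gaps = 10,
                      gap_len_range = c(300, 800), seed = 21)
sim <- make_donors(sim, k_list = c(37, 77, 117), contig_len = 10000, seed = 21)
res <- patch_gaps(sim$gapped, sim$donors)
table(res$patches$status)
identical(unclass(res$assembly), unclass(sim$truth))
```

## Redundancy removal

Scaffolds shorter than 200 kb are screened against strictly larger retained
scaffolds, smallest first, so a chain A ⊂ B ⊂ C with B removed still tests A
against C. Candidate placements come from exact 31-mers sampled every 500 bp
along the query; each candidate is verified with a containment alignment
(query global, target local, via `Biostrings::pairwiseAlignment`). Identity
is matches divided by alignment columns, gap columns included, and the
containment form itself enforces 100% query coverage in a single alignment —
the "fully aligned" reading, with no split hits. Queries with a hit at
identity ≥ 99% are removed; retained scaffolds keep their input order.

## Assembly statistics

L50 is the smallest k such that the k largest scaffolds reach half the total
length; N50 is the k-th largest length. Contig statistics are computed after
splitting scaffolds at N-runs of length ≥ `min_run`. The gap definition is
deliberately permissive — any run of ≥ 1 N is a gap by default — because
different assemblers emit different N-run conventions; `min_run` makes the
convention explicit and reproducible. GC excludes N from both numerator and
denominator. IUPAC ambiguity codes other than N are accepted on input but
converted to N with a warning, so gap and GC accounting stay well defined.

## Annotation QC

The filter keeps transcripts whose predicted protein has a homology
(protein-database) hit *or* a domain/signature hit, *and* whose curation
status is Annotated or Mapped. The conjunction is the strict reading of the
rule; because the disjunctive reading ("any support at all") is also
defensible, it is available as `rule = "or"`. Filtering is id-based:
transcript identity is the intended selector, and interval overlap (the
route taken by coordinate-based tools) adds nothing but ambiguity once ids
are in hand. Gene-level lines survive iff at least one child transcript
survives.

## Admixture screening

**Locus extraction.** Each ~120 bp bait is mapped with the same seeded
search (identity ≥ 0.8, both strands); baits with a unique best hit yield a
2,500 bp slice centered on the hit midpoint — centering follows the
convention of probe-based UCE harvesting workflows — reverse-complemented
to bait orientation and clamped (and flagged) at scaffold ends. A tie for
the best location skips the bait as ambiguous.

**Trimming to reference loci.** A sample's slice is aligned to the
majority-rule consensus of the reference per-locus alignment (match +1,
mismatch −1, gap −2, ends free) and projected into the reference columns:
overhangs are discarded, uncovered columns come back as missing, sample
insertions are dropped. An alignment scoring below a floor (a quarter of
the alignment length by default) rejects the locus for that sample.

**Genotype matrix.** Only biallelic columns are kept; N and gaps are
missing; the major allele codes 0 (ties broken alphabetically). Calls are
haploid by default because the focal system shows zero within-locus
heterozygosity at these loci — a consequence of generations of drift within
the hybrid zone rather than of recent F1/F2 hybridization; diploid 0/1/2
matrices are accepted by the factorization directly (three one-hot
categories per site).

**Diagnostic ranking.** Loci are ranked by the mean absolute
allele-frequency differential of their sites between the two labeled
populations; fixed differences score 1. This ranking stands in for the
geographic-cline-width screen used to define diagnostic loci in hybrid-zone
studies: both orderings put fixed differences first.

**Ancestry estimation.** The one-hot genotype matrix is factorized as
X ≈ QG by alternating least squares, 100 iterations by default: G solved
per site over the samples observed there, negatives clamped, category
frequencies renormalized per site; Q solved per sample over its observed
sites (optional ridge `alpha`, default 0 — no sparsity penalty is assumed)
and projected onto the probability simplex by the exact sort-and-threshold
projection (clamping and renormalizing is *not* the Euclidean projection
and is not used). Missing sites simply drop out of both solves rather than
being imputed. Initialization is a seeded flat Dirichlet, so runs are
bit-reproducible; iteration stops early when the squared-error loss changes
by < 1e-8. The spatially explicit variant of this estimator family is out
of scope: only the non-spatial factorization is implemented, which is the
component that produces ancestry coefficients.

```{r snmf-demo}
pops <- simulate_populations(n_per_pop = 20, n_loci = 12, locus_len = 300,
                             fixed_diffs_per_locus = 2, seed = 3)
hyb <- simulate_admixed(pops, q = 0.59, n_individuals = 5, seed = 3)
gm <- build_genotype_matrix(hyb$loci, pop_labels = hyb$labels)
fit <- snmf_ancestry(gm, K = 2, iterations = 100, seed = 3)
round(fit$Q[hyb$hybrids$sample, ], 3)
```

## What the simulator does and does not emulate

`simulate_genome` draws i.i.d. bases at GC 0.405 (the focal assembly's
composition). `introduce_gaps` places non-overlapping N-runs at least 2 kb
apart and 1.5 kb from scaffold ends so that full-length flanks stay clean,
recording each hidden sequence; restoring them reconstructs the truth
exactly. `make_donors` tiles the truth into contigs with a random phase per
k-mer label and applies i.i.d. substitutions. Gaps designated uncoverable
have their hidden spans excised from every donor — contigs are cut at those
spans rather than deleted whole, because deleting whole contigs would
collaterally remove coverage of neighboring *coverable* gaps (contigs are
longer than the minimum gap separation) and make the coverable flag
unreliable as ground truth. `simulate_populations` plants a stated number
of fixed differences per locus plus low-frequency within-population
polymorphism, all haploid; `simulate_admixed` copies each hybrid's
per-locus haplotype from a population-1 parent with probability q. All
randomness flows from one user seed through named substreams, so fixtures
are bit-stable.

What this does **not** emulate: real repeat structure (the main source of
ambiguous flank mappings), indel and chimera errors in donor assemblies,
linkage between loci, within-locus recombination in hybrids, and
heterozygous diploid genotypes. Passing tests therefore demonstrate the
correctness of the algorithms under clean, identifiable conditions — not
the error profile of a real 1.7 Gb snake assembly, whose headline numbers
(tens of thousands of gaps filled, N50 of ~22 Mb) arise from ~70×
real data and external tools.

## Study-scale choices

The test and analysis scale — a 1 Mb genome with 50 gaps of 500–2,000 bp,
nine donors at k = 37…117, 10 kb donor contigs; panels of 68 + 68
parental individuals at 20 diagnostic loci of 600 bp with 2 fixed
differences each — was chosen once as a desk-scale miniature of the study
system (136-individual two-species panel, top-20 diagnostic UCE loci) and
is stated here so results are interpretable; it is small enough for a
single CPU yet large enough that seeds are unique and frequency estimates
are stable.

Two statistical points about the admixture emulation. First, a single
hybrid's realized ancestry across 20 independently drawn loci has binomial
standard deviation ≈ 0.11 around q; no estimator can pin a one-individual
estimate into a narrow band for every seed. The end-to-end check therefore
reports the mean coefficient over a cohort of 50 simulated hybrids (standard
error ≈ 0.016), which tests the same structural claim — that a q = 0.59
specimen is recovered as such. Second, the least-squares factorization has
a known finite-sample behavior: samples with extreme ancestry are projected
onto the simplex vertices and the frequency matrix G absorbs the residual,
so against Dirichlet-distributed truth at n = 50 its mean absolute error
(~0.057) sits above the pure binomial sampling floor (~0.030); against the
realized per-site ancestry it is ~0.045. This is a property of the
least-squares objective itself — its global optimum is at the saturated
solution — not of the implementation, and it disappears as parental panels
anchor G (the realistic screening design, where recovery error drops below
0.01 of the realized fraction).

## Known limitations

* The flank search's seeded candidate generation bounds sensitivity at high
  divergence (documented above); an exhaustive scan would remove the bound
  at ~30× the cost.
* Containment identity uses one global containment alignment; tiled
  partial hits (split HSPs) never count toward coverage, which is the
  strict reading of "fully aligned" but stricter than some local aligners
  report.
* Residual gaps after patching are reported, not filled; a k-mer-walk
  second-pass filler can be slotted in downstream.
* Ancestry estimation is non-spatial and reports a loss-versus-K curve
  rather than cross-validated model choice for K.
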