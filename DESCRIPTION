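Package: gapatch
Title: Draft-Genome Finishing and Admixture Screening for a Linked-Read Snake Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages used to finish and
    screen a linked-read draft genome: flank-anchored patching of N-run gaps
    using shotgun donor assemblies built at several k-mer sizes (larger k
    preferred), removal of redundant scaffolds fully contained in larger ones,
    assembly statistics (N50/L50, GC, gap accounting), quality filtering of
    predicted-gene annotations by functional-annotation support, extraction of
    ultraconserved-element (UCE) loci around capture baits, and ancestry
    estimation of a sequenced specimen by least-squares sparse nonnegative
    matrix factorization of a diagnostic-locus genotype matrix. Includes
    seeded simulators for gapped genomes with donor contig sets and for
    two-population UCE panels with admixed individuals, so every stage is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
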