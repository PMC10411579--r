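# gapatch

Finishing a linked-read draft genome and screening its specimen for
admixture — as a tested, reusable R package plus a scripted analysis.

## What this is for

Large-genome projects built on 10X Chromium linked reads typically end up
with a scaffold assembly full of N-run gaps, several shotgun assemblies of
the same reads at different k-mer sizes, a predicted gene set in need of
quality control, and — for wild-caught specimens from contact zones — an
open question about whether the individual itself is admixed. `gapatch`
implements the computational stages that connect those pieces:

* **Flank-anchored gap patching.** For each gap, N-free flanks of
  decreasing length (1 kb → 100 bp, steps of 100) are mapped into donor
  shotgun contigs by a seeded edit-distance search (both strands, edit
  distance ≤ 10% of flank length, unambiguous best hit). When both flanks
  land in the same contig, same strand, in order, the region between the
  outermost coordinates replaces the gap and its flanks — donors of larger
  k-mer size taking priority.
* **Redundant-scaffold removal.** Scaffolds < 200 kb that fully align
  within a larger scaffold at ≥ 99% identity (matches / alignment columns)
  are dropped, smallest first, against retained scaffolds only.
* **Assembly statistics.** N50/L50 (scaffold and contig), GC excluding N,
  gap counts, maxima.
* **Annotation QC.** Keep transcripts whose predicted protein has a
  homology or domain hit AND an Annotated/Mapped curation status; filter
  the GTF to those ids and emit their coordinates as BED6.
* **Admixture screening.** Slice 2,500 bp around UCE capture baits, trim
  slices to reference locus alignments, build a biallelic haploid genotype
  matrix, rank loci by between-population allele-frequency differential,
  and estimate ancestry by least-squares sparse nonnegative matrix
  factorization: X ≈ QG with Q rows on the probability simplex (exact
  Euclidean projection), G per-site category frequencies, 100 alternating
  least-squares iterations, seeded Dirichlet initialization.
* **Synthetic data.** Seeded generators for gapped genomes with donor
  contig sets (known hidden sequence per gap, controllable coverage and
  error rate) and for two-population locus panels with fixed differences
  and admixed individuals of known ancestry fraction q — so every stage is
  testable against ground truth, offline.

The model at the core of the admixture stage: one-hot-encode haploid calls
(2 categories per biallelic site), then alternately solve least squares for
G (clamp negatives, renormalize each site's categories) and for Q (project
each row onto the simplex), tracking the squared-error loss. Per-individual
ancestry coefficients are the rows of Q.

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on simulated
inputs and write their tables under `results/`. For example:

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_patch_gaps.R
Rscript analysis/05_admixture.R
```

prints (seeds are fixed in the scripts):

```
gapped assembly:
scaffolds: 1 (N50 1e+06, L50 1, max 1,000,000)
contigs: 51 (N50 27,414, L50 12, max 75,581)
total 1,000,000 bp, GC 0.4045, gaps 50 (62,179 bp)

gaps filled: 50 of 50
patched assembly equals truth: TRUE
after:
contigs: 1 (N50 1e+06, L50 1, max 1,000,000)
total 1,000,000 bp, GC 0.4046, gaps 0 (0 bp)

genotype matrix: 186 samples x 100 sites; top-20 loci selected
hybrid cohort mean ancestry: 57.2% pop1 / 42.8% pop2 (true 59/41)
mean |q_hat - realized q| = 0.0448
```

Reading this: on a 1 Mb simulated genome with 50 gaps and error-free donor
assemblies at k = 37…117, every gap is patched and the patched sequence is
string-identical to the hidden truth (so contig N50 rises from 27 kb to the
full scaffold length). In the admixture emulation, 68 + 68 parental
individuals and 50 hybrids simulated at q = 0.59 over the 20 most
diagnostic loci are recovered at a mean coefficient of 57.2% — within
sampling error of the truth, and each hybrid's estimate tracks its realized
(drawn) ancestry to ~0.045.

The same functions work on real files: `read_fasta()` /
`donor_assembly()` / `patch_gaps()` for finishing, `read_gtf()` /
`read_status_table()` / `passing_transcripts()` for annotation QC,
`extract_uce_loci()` / `build_genotype_matrix()` / `snmf_ancestry()` for
screening.

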