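#!/usr/bin/env Rscript
# Annotation QC: keeps predicted transcripts whose proteins have a homology
# or domain hit AND an Annotated/Mapped curation status, then filters the
# GTF to those transcripts and writes their coordinates as BED6.

suppressPackageStartupMessages(library(gapatch))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gtf <- system.file("extdata", "toy_annotation.gtf", package = "gapatch")
status <- system.file("extdata", "toy_status.tsv", package = "gapatch")

rec <- read_gtf(gtf)
tab <- read_status_table(status)
keep <- passing_transcripts(tab)
filt <- filter_gtf_by_ids(rec, keep)
bed <- transcripts_to_bed(rec, keep)

write_gtf(filt, file.path(out, "annotation_filtered.gtf"))
write_bed(bed, file.path(out, "annotation_passing.bed"))

cat(sprintf("transcripts in GTF: %d; passing QC: %d\n",
            length(unique(rec$transcript_id[!is.na(rec$transcript_id)])),
            length(keep)))
cat("passing:", paste(keep, collapse = ", "), "\n")
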