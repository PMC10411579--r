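#!/usr/bin/env Rscript
# Redundant-scaffold screen: plants near-identical small copies and
# sub-threshold decoys in a simulated assembly, then removes scaffolds
# shorter than 200 kb that fully align to a larger scaffold at >= 99%
# identity. Writes the removal report and the filtered assembly.

suppressPackageStartupMessages(library(gapatch))
seed <- 104
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(seed)

substitute_n <- function(x, n) {
  chars <- strsplit(x, "")[[1]]
  pos <- sample(length(chars), n)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

main <- simulate_genome(5e5, seed = seed)[[1]]
seqs <- c(main = main)
for (i in 1:20) {   # redundant copies (half exact, half at 99.6%)
  len <- sample(2000:3000, 1); s0 <- sample(nchar(main) - len, 1)
  span <- substr(main, s0, s0 + len - 1)
  if (i %% 2 == 0) span <- substitute_n(span, round(0.004 * len))
  seqs[paste0("dup", i)] <- span
}
for (i in 1:20) {   # 98%-identity decoys that must survive
  len <- sample(2000:3000, 1); s0 <- sample(nchar(main) - len, 1)
  seqs[paste0("dec", i)] <- substitute_n(substr(main, s0, s0 + len - 1),
                                         round(0.02 * len))
}
a <- assembly(seqs)

r <- remove_redundant(a, max_len = 200000, min_identity = 0.99,
                      required_coverage = 1.0)
write_fasta(r$assembly, file.path(out, "deduplicated.fa"))
write.table(r$removed, file.path(out, "redundancy_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("removed %d of %d planted duplicates; %d of %d decoys retained\n",
            sum(grepl("^dup", r$removed$query_id)), 20,
            sum(grepl("^dec", names(r$assembly))), 20))
print(r$removed[seq_len(min(5, nrow(r$removed))), ])
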