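# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# N50/L50 by explicit accumulation over the descending-sorted lengths.
brute_nx <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(s)) / 2
  acc <- 0
  for (k in seq_along(s)) {
    acc <- acc + s[k]
    if (acc >= half) return(list(n50 = s[k], l50 = k))
  }
}

# Full global edit distance (unit costs), textbook DP.
edit_distance_dp <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- c(i, rep(0L, length(b)))
    for (j in seq_along(b)) {
      cur[j + 1] <- min(prev[j] + (a[i] != b[j]), prev[j + 1] + 1L,
                        cur[j] + 1L)
    }
    prev <- cur
  }
  prev[length(b) + 1]
}

# Minimum edit distance of pattern against any substring of text
# (semi-global scan; free text ends).
best_occurrence_dp <- function(pattern, text) {
  p <- strsplit(pattern, "")[[1]]; t <- strsplit(text, "")[[1]]
  prev <- rep(0L, length(t) + 1)
  for (i in seq_along(p)) {
    cur <- c(i, rep(0L, length(t)))
    for (j in seq_along(t)) {
      cur[j + 1] <- min(prev[j] + (p[i] != t[j]), prev[j + 1] + 1L,
                        cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

# Random-base helpers for fixtures.
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_oracle <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Substitute exactly n bases of x at distinct positions (never to the same
# base), returning the mutated string.
substitute_n <- function(x, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(x, "")[[1]]
  pos <- sample(length(chars), n)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Toy two-gene / four-transcript GTF used by the annotation tests.
toy_gtf_lines <- function() {
  c('chr1\ttest\tgene\t100\t900\t.\t+\t.\tgene_id "g1";',
    'chr1\ttest\ttranscript\t100\t500\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\ttest\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\ttest\tCDS\t120\t200\t.\t+\t0\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\ttest\ttranscript\t600\t900\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t2";',
    'chr1\ttest\texon\t600\t900\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t2";',
    'chr2\ttest\tgene\t50\t800\t.\t-\t.\tgene_id "g2";',
    'chr2\ttest\ttranscript\t50\t400\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t1";',
    'chr2\ttest\texon\t50\t400\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t1";',
    'chr2\ttest\ttranscript\t500\t800\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t2";',
    'chr2\ttest\texon\t500\t800\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t2";')
}
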