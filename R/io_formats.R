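#' Construct an assembly from named sequences
#'
#' An assembly is a named character vector of uppercase scaffold sequences
#' over the alphabet A/C/G/T/N. Scaffold ids must be non-empty and unique;
#' every sequence must have length at least 1. IUPAC ambiguity codes other
#' than N are accepted but converted to N with a warning, since downstream
#' gap and GC accounting treats them as unknown bases.
#'
#' @param seqs named character vector of sequences (any case).
#' @return named character vector of class \code{"assembly"}.
#' @export
assembly <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every scaffold must have a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate scaffold id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L)) stop("zero-length scaffold sequence")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    iupac <- grepl("^[ACGTNRYSWKMBDHV]*$", seqs[bad])
    if (!all(iupac))
      stop("non-nucleotide characters in scaffold(s): ",
           paste(ids[bad][!iupac], collapse = ", "))
    warning("IUPAC ambiguity codes converted to N in ",
            sum(bad), " scaffold(s)")
    seqs[bad] <- gsub("[RYSWKMBDHV]", "N", seqs[bad])
  }
  structure(seqs, class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("assembly:", length(x), "scaffold(s),",
      format(sum(nchar(x)), big.mark = ","), "bp\n")
  invisible(x)
}

#' @export
`[.assembly` <- function(x, i) {
  structure(unclass(x)[i], class = "assembly")
}

#' Read a FASTA file into an assembly
#'
#' @param path path to a (multi-)FASTA file.
#' @return an \code{\link{assembly}}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  first <- which(nzchar(trimws(lines)) & !startsWith(lines, ";"))[1]
  if (!is.na(first) && !startsWith(lines[first], ">"))
    stop("malformed FASTA at line ", first, ": sequence before header")
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  assembly(seqs)
}

#' Write an assembly as FASTA
#'
#' @param x an assembly (or named character vector).
#' @param path output path.
#' @param width line-wrap width in columns.
#' @export
write_fasta <- function(x, path, width = 80L) {
  ids <- names(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", ids[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Find N-run gaps in a scaffold or assembly
#'
#' A gap is a maximal run of at least \code{min_run} N characters.
#' Coordinates are 0-based half-open.
#'
#' @param x an assembly, or a single (optionally named) sequence.
#' @param min_run minimum N-run length to call a gap.
#' @return data.frame with columns scaffold_id, start, end, length,
#'   sorted by scaffold then start.
#' @export
find_gaps <- function(x, min_run = 1L) {
  stopifnot(min_run >= 1L)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  out <- lapply(seq_along(x), function(i) {
    m <- gregexpr(sprintf("N{%d,}", min_run), toupper(x[[i]]))[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(scaffold_id = names(x)[i],
               start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out
}

# N50/L50 of a length multiset: L50 is the smallest k such that the k
# largest lengths sum to at least half the total; N50 is the k-th largest.
nx_stats <- function(lengths, frac = 0.5) {
  if (length(lengths) == 0L) return(list(nx = NA_integer_, lx = NA_integer_))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  k <- which(cumsum(s) >= sum(s) * frac)[1]
  list(nx = s[k], lx = k)
}

#' Assembly summary statistics
#'
#' Scaffold and contig N50/L50, GC fraction (N excluded from numerator and
#' denominator), gap counts and maxima. Contigs are the segments obtained by
#' splitting scaffolds at N-runs of length >= \code{min_run}.
#'
#' @param x an assembly.
#' @param min_run minimum N-run length treated as a gap.
#' @return list of class \code{"assembly_stats"}.
#' @export
assembly_stats <- function(x, min_run = 1L) {
  scaf_len <- nchar(x)
  gaps <- find_gaps(x, min_run)
  if (length(x) == 0L) {
    return(structure(list(total_length = 0, n_scaffolds = 0L, n_contigs = 0L,
                          scaffold_N50 = NA_real_, scaffold_L50 = NA_integer_,
                          contig_N50 = NA_real_, contig_L50 = NA_integer_,
                          max_scaffold = 0, max_contig = 0,
                          gc_fraction = NA_real_, n_gaps = 0L, gap_bp = 0),
                     class = "assembly_stats"))
  }
  contig_len <- unlist(lapply(x, function(s) {
    pieces <- strsplit(s, sprintf("N{%d,}", min_run))[[1]]
    nchar(pieces[nzchar(pieces)])
  }), use.names = FALSE)
  all_seq_n <- sum(scaf_len)
  n_bases <- sum(nchar(gsub("[^N]", "", x)))
  gc <- sum(nchar(gsub("[^GC]", "", x)))
  sc <- nx_stats(scaf_len)
  co <- nx_stats(contig_len)
  structure(list(
    total_length = all_seq_n,
    n_scaffolds = length(x),
    n_contigs = length(contig_len),
    scaffold_N50 = sc$nx, scaffold_L50 = sc$lx,
    contig_N50 = co$nx, contig_L50 = co$lx,
    max_scaffold = max(scaf_len), max_contig = max(contig_len),
    gc_fraction = if (all_seq_n > n_bases) gc / (all_seq_n - n_bases) else NA_real_,
    n_gaps = nrow(gaps), gap_bp = sum(gaps$length)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "scaffolds: %d (N50 %s, L50 %s, max %s)\ncontigs: %d (N50 %s, L50 %s, max %s)\ntotal %s bp, GC %.4f, gaps %d (%s bp)\n",
    x$n_scaffolds, format(x$scaffold_N50, big.mark = ","), x$scaffold_L50,
    format(x$max_scaffold, big.mark = ","),
    x$n_contigs, format(x$contig_N50, big.mark = ","), x$contig_L50,
    format(x$max_contig, big.mark = ","),
    format(x$total_length, big.mark = ","), x$gc_fraction,
    x$n_gaps, format(x$gap_bp, big.mark = ",")))
  invisible(x)
}

#' @rdname assembly_stats
#' @param ... unused.
#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

gtf_attr <- function(attributes, key) {
  m <- regmatches(attributes,
                  regexpr(sprintf('%s "?[^";]+"?', key), attributes))
  out <- rep(NA_character_, length(attributes))
  hit <- regexpr(sprintf('%s "?[^";]+"?', key), attributes) > 0
  out[hit] <- gsub(sprintf('^%s "?|"$', key), "", m)
  out
}

#' Read a GTF annotation file
#'
#' Parses a 9-column tab-separated GTF. The attribute string is preserved
#' verbatim; \code{transcript_id} and \code{gene_id} are additionally parsed
#' out for filtering. Comment lines (\code{#}) and blank lines are skipped.
#'
#' @param path path to a GTF file.
#' @return data.frame with the nine GTF columns plus transcript_id, gene_id.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("GTF parse error at line ", lineno[which(nf != 9L)[1]],
         ": expected 9 tab-separated columns, found ", nf[nf != 9L][1])
  m <- do.call(rbind, fields)
  rec <- data.frame(seqname = m[, 1], source = m[, 2], feature = m[, 3],
                    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                    score = m[, 6], strand = m[, 7], frame = m[, 8],
                    attributes = m[, 9], stringsAsFactors = FALSE)
  if (any(rec$start > rec$end))
    stop("GTF record with start > end at line ",
         lineno[which(rec$start > rec$end)[1]])
  rec$transcript_id <- gtf_attr(rec$attributes, "transcript_id")
  rec$gene_id <- gtf_attr(rec$attributes, "gene_id")
  rec
}

#' Write GTF records
#'
#' @param records data.frame as returned by \code{\link{read_gtf}}.
#' @param path output path.
#' @export
write_gtf <- function(records, path) {
  lines <- with(records, paste(seqname, source, feature, start, end,
                               score, strand, frame, attributes, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
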