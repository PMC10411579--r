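#' Read a functional-annotation status table
#'
#' Tab-separated with header columns transcript_id, has_homology_hit,
#' has_domain_hit, curation_status. Boolean columns accept TRUE/FALSE, T/F,
#' 1/0, yes/no. Unknown curation statuses are recorded as "Other" with a
#' warning.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per transcript.
#' @export
read_status_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("transcript_id", "has_homology_hit", "has_domain_hit",
              "curation_status")
  if (!all(needed %in% names(tab)))
    stop("status table must have columns: ", paste(needed, collapse = ", "))
  as_bool <- function(v) {
    if (is.logical(v)) return(v)
    tolower(as.character(v)) %in% c("true", "t", "1", "yes", "y")
  }
  tab$has_homology_hit <- as_bool(tab$has_homology_hit)
  tab$has_domain_hit <- as_bool(tab$has_domain_hit)
  validate_status_table(tab)
}

validate_status_table <- function(tab) {
  if (anyDuplicated(tab$transcript_id))
    stop("duplicate transcript_id in status table")
  known <- c("Annotated", "Mapped", "Blasted", "NoHit", "Other")
  bad <- !tab$curation_status %in% known
  if (any(bad)) {
    warning("unknown curation status value(s) recorded as Other: ",
            paste(unique(tab$curation_status[bad]), collapse = ", "))
    tab$curation_status[bad] <- "Other"
  }
  tab
}

#' Transcripts passing functional-annotation QC
#'
#' The default rule keeps transcripts whose predicted protein has a protein
#' database (homology) hit OR a domain/signature hit, AND whose curation
#' status is Annotated or Mapped. \code{rule = "or"} instead keeps
#' transcripts satisfying any of the three conditions.
#'
#' @param table status table (see \code{\link{read_status_table}}).
#' @param rule "and" (default) or "or", see Details.
#' @return character vector of passing transcript ids.
#' @export
passing_transcripts <- function(table, rule = c("and", "or")) {
  rule <- match.arg(rule)
  table <- validate_status_table(table)
  hit <- table$has_homology_hit | table$has_domain_hit
  curated <- table$curation_status %in% c("Annotated", "Mapped")
  keep <- if (rule == "and") hit & curated else hit | curated
  table$transcript_id[keep]
}

#' Filter GTF records to a set of transcripts
#'
#' Keeps every feature whose transcript_id is in \code{keep_ids}. Gene-level
#' features (no transcript_id) are retained iff at least one of their child
#' transcripts is retained. Line order is preserved.
#'
#' @param records data.frame from \code{\link{read_gtf}}.
#' @param keep_ids character vector of transcript ids to keep.
#' @return filtered data.frame.
#' @export
filter_gtf_by_ids <- function(records, keep_ids) {
  has_tid <- !is.na(records$transcript_id)
  keep <- has_tid & records$transcript_id %in% keep_ids
  kept_genes <- unique(records$gene_id[keep])
  gene_keep <- !has_tid & !is.na(records$gene_id) &
    records$gene_id %in% kept_genes
  records[keep | gene_keep, , drop = FALSE]
}

#' Transcript coordinates as BED6
#'
#' One BED line per kept transcript feature; GTF 1-based inclusive
#' coordinates become 0-based half-open.
#'
#' @param records data.frame from \code{\link{read_gtf}}.
#' @param keep_ids transcript ids to emit (default: all transcript features).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
transcripts_to_bed <- function(records, keep_ids = NULL) {
  tx <- records[records$feature == "transcript" & !is.na(records$transcript_id), ,
                drop = FALSE]
  if (!is.null(keep_ids)) tx <- tx[tx$transcript_id %in% keep_ids, , drop = FALSE]
  data.frame(chrom = tx$seqname, start = tx$start - 1L, end = tx$end,
             name = tx$transcript_id, score = ".", strand = tx$strand,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write BED records
#'
#' @param bed data.frame from \code{\link{transcripts_to_bed}}.
#' @param path output path.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
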