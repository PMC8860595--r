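# Genomic intervals are represented throughout as plain data.frames with
# columns chrom, start, end, strand in 0-based half-open coordinates
# [start, end), strand mandatory ("+" or "-").  All 3' end data are
# strand-specific, so every overlap operation here matches strands.

#' Construct a genomic interval table
#'
#' Validates and returns a data.frame of strand-specific genomic intervals in
#' the package-wide convention: 0-based, half-open `[start, end)`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end` (half-open).
#' @param strand Character vector, each element `"+"` or `"-"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr1", 10, 20, "+")
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval must satisfy start < end (half-open)")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

#' Strand-specific interval overlap
#'
#' Returns all subject intervals on the same strand sharing at least one
#' nucleotide with each query under half-open semantics, via
#' [GenomicRanges::findOverlaps()].
#'
#' @param query,subjects Interval data.frames (`chrom`, `start`, `end`,
#'   `strand`, 0-based half-open).
#' @return A data.frame with columns `query` and `subject` (row indices).
#' @examples
#' q <- genomic_interval("chr1", 10, 20, "+")
#' s <- genomic_interval(c("chr1", "chr1"), c(19, 20), c(30, 40), c("+", "+"))
#' overlap_any(q, s)   # hits only the first subject: [10,20) vs [20,40) is empty
#' @export
overlap_any <- function(query, subjects) {
  validate_intervals(query); validate_intervals(subjects)
  if (nrow(query) == 0 || nrow(subjects) == 0) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  # suppress the benign "no sequence levels in common" warning: disjoint
  # chromosome sets simply mean no hits
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_to_granges(query), intervals_to_granges(subjects),
    ignore.strand = FALSE
  ))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}
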