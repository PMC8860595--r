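# Library-size normalization anchored on last exons of protein-coding
# genes, which are assumed insensitive to exosome/adaptor depletion: bulk
# mRNA 3' ends should not move, so their summed signal calibrates depth.

#' Last-exon count matrix
#'
#' Sums each raw track's 3' end counts within the last exon of every
#' protein-coding gene (strand-matched).
#'
#' @param tracks Named list of raw `end_track` objects (names are ignored;
#'   `library_id` attributes are used as column names).
#' @param ann An `annotation` object with at least one protein-coding gene.
#' @return Numeric matrix, last exon (rownames = gene id) x library.
#' @export
last_exon_matrix <- function(tracks, ann) {
  stopifnot(inherits(ann, "annotation"))
  if (any(vapply(tracks, function(t) isTRUE(t$normalized), logical(1))))
    stop("last_exon_matrix expects raw (unnormalized) tracks")
  pc <- ann$genes$gene_id[ann$genes$biotype == "protein_coding"]
  if (length(pc) == 0) stop("annotation contains no protein-coding genes")
  le <- ann$last_exons[ann$last_exons$gene_id %in% pc, , drop = FALSE]
  m <- vapply(tracks, function(t) sum_in_intervals(t, le),
              numeric(nrow(le)))
  m <- matrix(m, nrow = nrow(le),
              dimnames = list(le$gene_id,
                              vapply(tracks, `[[`, "", "library_id")))
  m
}

#' Filter for expressed rows
#'
#' Keeps rows whose maximum over libraries is strictly greater than
#' `min_reads` (so a row maxing at exactly `min_reads` is dropped).
#'
#' @param m Count matrix (rows = features, columns = libraries).
#' @param min_reads Expression threshold; default 100.
#' @return The filtered matrix.
#' @export
filter_expressed <- function(m, min_reads = 100) {
  keep <- apply(m, 1, max) > min_reads
  if (!any(keep))
    stop("no rows exceed min_reads = ", min_reads,
         "; lower the threshold or check library depth")
  m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' After adding a pseudocount, each row's reference is its geometric mean
#' across libraries and a library's size factor is the median over rows of
#' count/reference.  Even-length medians use the lower of the two central
#' values (lower-median convention) for bit-reproducibility.
#'
#' @param m Filtered count matrix (>= 1 row, >= 2 libraries).
#' @param pseudocount Added to every count before ratio calculation;
#'   default 1.  With `pseudocount = 0`, rows containing zeros drop out of
#'   the median (classic median-of-ratios).
#' @return Named numeric vector of positive size factors, one per library.
#' @export
size_factors <- function(m, pseudocount = 1) {
  if (nrow(m) < 1) stop("size_factors needs >= 1 row")
  if (ncol(m) < 2) stop("size_factors needs >= 2 libraries")
  mp <- m + pseudocount
  if (pseudocount == 0) {
    ok <- apply(mp > 0, 1, all)
    mp <- mp[ok, , drop = FALSE]
    if (nrow(mp) == 0) stop("no rows with all-positive counts at pseudocount 0")
  }
  logref <- rowMeans(log(mp))
  sf <- apply(mp, 2, function(col) {
    r <- sort(exp(log(col) - logref))
    n <- length(r)
    r[ceiling(n / 2)]      # lower median for even n
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor; a library may have all-zero counts ",
         "after filtering")
  sf
}

#' Apply size factors
#'
#' Divides a track's values or a count matrix's columns by the library's
#' size factor; tracks are flagged as normalized.
#'
#' @param x An `end_track` or a cluster/exon count matrix with library
#'   column names.
#' @param sf Named size-factor vector covering every library in `x`.
#' @return Object of the same shape with normalized values.
#' @export
normalize_counts <- function(x, sf) {
  if (inherits(x, "end_track")) {
    if (!(x$library_id %in% names(sf)))
      stop("no size factor for library ", x$library_id)
    dt <- data.table::copy(x$counts)
    dt[, value := value / sf[[x$library_id]]]
    return(end_track(dt, x$library_id, normalized = TRUE))
  }
  if (is.matrix(x)) {
    missing <- setdiff(colnames(x), names(sf))
    if (length(missing))
      stop("no size factor for libraries: ", paste(missing, collapse = ", "))
    return(sweep(x, 2, sf[colnames(x)], "/"))
  }
  stop("normalize_counts handles end_track or matrix inputs")
}
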