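# Transcriptome annotation container.  One representative transcript per gene
# is assumed (validated on read); introns, splice-acceptor (SA) positions and
# last exons are derived, never stored redundantly in the input.
#
# Conventions (all 0-based half-open, strand-aware):
#   * TSS  = first transcribed nucleotide (start on "+", end-1 on "-").
#   * pA   = last transcribed nucleotide (end-1 on "+", start on "-").
#   * SA   = first nucleotide of the exon downstream of an intron in
#            transcription orientation (intron end on "+", intron start-1 on
#            "-"); excised-intron 3' ends accumulate immediately upstream of
#            it (transcription-orientation offset -1).

new_annotation <- function(genes, exons, introns, last_exons,
                           seqlengths = NULL) {
  structure(
    list(genes = genes, exons = exons, introns = introns,
         last_exons = last_exons, seqlengths = seqlengths),
    class = "annotation"
  )
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation>", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$introns), "introns (",
      sum(x$introns$snoRNA_hosting), "snoRNA-hosting ),",
      nrow(x$last_exons), "last exons\n")
  cat("  biotypes:",
      paste(names(table(x$genes$biotype)), table(x$genes$biotype),
            sep = ":", collapse = " "), "\n")
  invisible(x)
}

ANN_BIOTYPES <- c("protein_coding", "lncRNA", "PROMPT", "eRNA", "snoRNA",
                  "not_annotated")

#' Read a transcriptome annotation from GTF or BED12
#'
#' Parses gene models via [rtracklayer::import()] and derives the quantities
#' downstream stages need: introns (the gaps between consecutive exons of a
#' gene), strand-aware splice-acceptor positions, TSS/pA positions, last
#' exons, and snoRNA-hosting intron flags (a gene of biotype `snoRNA` lying
#' strictly inside an intron of a same-strand host marks that intron as
#' hosting).  GTF coordinates (1-based closed) are converted to the internal
#' 0-based half-open convention on read.
#'
#' Biotype is taken from the `gene_biotype` (or `biotype`/`gene_type`)
#' attribute and defaults to `not_annotated`.  Exons of a gene must be
#' non-overlapping; overlapping exons raise a validation error.
#'
#' @param path Path to a `.gtf` or BED12 `.bed` file.
#' @return An `annotation` object: a list with data.frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`, `biotype`, `tss`, `pas`),
#'   `exons`, `introns` (`length`, `sa_pos`, `snoRNA_hosting`, `sno_start`,
#'   `sno_end`), `last_exons`, and optional `seqlengths`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e))
  )
  if (fmt == "gtf") {
    build_annotation_from_gtf(gr)
  } else {
    build_annotation_from_bed12(gr)
  }
}

build_annotation_from_gtf <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0) stop("annotation contains no exon records")
  mce <- S4Vectors::mcols(ex)
  gene_id <- as.character(mce$gene_id)
  if (any(is.na(gene_id))) stop("exon records lacking gene_id")
  bio_col <- intersect(c("gene_biotype", "biotype", "gene_type"), names(mce))
  biotype <- if (length(bio_col)) as.character(mce[[bio_col[1]]]) else
    rep(NA_character_, length(ex))
  biotype[is.na(biotype) | !(biotype %in% ANN_BIOTYPES)] <- "not_annotated"
  tx <- if ("transcript_id" %in% names(mce))
    as.character(mce$transcript_id) else gene_id
  ntx <- tapply(tx, gene_id, function(z) length(unique(z[!is.na(z)])))
  if (any(ntx > 1))
    stop("multiple transcripts per gene not supported; genes: ",
         paste(head(names(ntx)[ntx > 1], 3), collapse = ", "))
  exons <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  derive_annotation(exons)
}

build_annotation_from_bed12 <- function(gr) {
  blocks <- S4Vectors::mcols(gr)$blocks
  name <- S4Vectors::mcols(gr)$name
  if (is.null(name)) name <- paste0("gene_", seq_along(gr))
  rows <- lapply(seq_along(gr), function(i) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    st <- as.character(GenomicRanges::strand(gr))[i]
    if (!is.null(blocks)) {
      b <- blocks[[i]]
      data.frame(gene_id = name[i], chrom = ch,
                 start = GenomicRanges::start(b) - 1L,
                 end = GenomicRanges::end(b),
                 strand = st, biotype = "not_annotated",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = name[i], chrom = ch,
                 start = GenomicRanges::start(gr)[i] - 1L,
                 end = GenomicRanges::end(gr)[i],
                 strand = st, biotype = "not_annotated",
                 stringsAsFactors = FALSE)
    }
  })
  derive_annotation(do.call(rbind, rows))
}

# exons: data.frame(gene_id, chrom, start, end, strand, biotype); 0-based.
derive_annotation <- function(exons, seqlengths = NULL) {
  validate_intervals(exons)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  split_ex <- split(exons, exons$gene_id)

  gene_rows <- list(); intron_rows <- list(); last_rows <- list()
  for (gid in names(split_ex)) {
    e <- split_ex[[gid]]
    if (length(unique(e$strand)) != 1 || length(unique(e$chrom)) != 1)
      stop("gene ", gid, " has exons on multiple strands/chromosomes")
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in gene ", gid)
    st <- e$strand[1]; ch <- e$chrom[1]
    gstart <- min(e$start); gend <- max(e$end)
    tss <- if (st == "+") gstart else gend - 1L
    pas <- if (st == "+") gend - 1L else gstart
    gene_rows[[gid]] <- data.frame(
      gene_id = gid, chrom = ch, start = gstart, end = gend, strand = st,
      biotype = e$biotype[1], tss = tss, pas = pas, stringsAsFactors = FALSE)
    # last exon = 3'-most exon in transcription orientation
    le <- if (st == "+") e[nrow(e), ] else e[1, ]
    last_rows[[gid]] <- data.frame(
      gene_id = gid, chrom = ch, start = le$start, end = le$end, strand = st,
      stringsAsFactors = FALSE)
    if (nrow(e) > 1) {
      is_ <- e$end[-nrow(e)]; ie_ <- e$start[-1]
      sa <- if (st == "+") ie_ else is_ - 1L
      intron_rows[[gid]] <- data.frame(
        gene_id = gid,
        intron_id = paste0(gid, ".I", seq_along(is_)),
        chrom = ch, start = is_, end = ie_, strand = st,
        length = ie_ - is_, sa_pos = sa,
        snoRNA_hosting = FALSE,
        sno_start = NA_integer_, sno_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows); rownames(genes) <- NULL
  last_exons <- do.call(rbind, last_rows); rownames(last_exons) <- NULL
  introns <- if (length(intron_rows)) do.call(rbind, intron_rows) else
    data.frame(gene_id = character(0), intron_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), length = integer(0),
               sa_pos = integer(0), snoRNA_hosting = logical(0),
               sno_start = integer(0), sno_end = integer(0))
  rownames(introns) <- NULL

  # flag snoRNA-hosting introns: a snoRNA gene strictly inside a same-strand
  # intron of another gene
  sno <- genes[genes$biotype == "snoRNA", , drop = FALSE]
  if (nrow(sno) > 0 && nrow(introns) > 0) {
    hits <- overlap_any(sno[, c("chrom", "start", "end", "strand")],
                        introns[, c("chrom", "start", "end", "strand")])
    for (k in seq_len(nrow(hits))) {
      s <- sno[hits$query[k], ]; i <- hits$subject[k]
      if (s$start > introns$start[i] && s$end < introns$end[i] &&
          s$gene_id != introns$gene_id[i]) {
        introns$snoRNA_hosting[i] <- TRUE
        introns$sno_start[i] <- s$start
        introns$sno_end[i] <- s$end
      }
    }
  }
  new_annotation(genes, exons, introns, last_exons, seqlengths)
}

#' Write an annotation to GTF
#'
#' Emits one `gene` and per-exon `exon` records (with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes) in standard 1-based closed
#' GTF coordinates.  `read_annotation(write_annotation(ann))` reproduces the
#' derived gene models.
#'
#' @param ann An `annotation` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "annotation"))
  g <- ann$genes; e <- ann$exons
  attr_str <- function(gid, bio) sprintf(
    'gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";', gid, gid, bio)
  gene_lines <- sprintf("%s\texosens\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$start + 1L, g$end, g$strand,
                        attr_str(g$gene_id, g$biotype))
  exon_lines <- sprintf("%s\texosens\texon\t%d\t%d\t.\t%s\t.\t%s",
                        e$chrom, e$start + 1L, e$end, e$strand,
                        attr_str(e$gene_id, e$biotype))
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}

#' Splice-acceptor anchor set
#'
#' Extracts oriented SA anchor points with intron metadata for metagene
#' profiling and feature stratification.
#'
#' @param ann An `annotation` object.
#' @param hosting `NULL` for all introns, `TRUE` for snoRNA-hosting introns
#'   only, `FALSE` for regular introns only.
#' @return A data.frame with columns `chrom`, `pos` (SA position, 0-based),
#'   `strand`, `kind` (`"SA"`), `intron_length`, `length_class`,
#'   `snoRNA_hosting`, `gene_id`, `intron_id`.
#' @export
sa_anchors <- function(ann, hosting = NULL) {
  stopifnot(inherits(ann, "annotation"))
  i <- ann$introns
  if (!is.null(hosting)) i <- i[i$snoRNA_hosting == hosting, , drop = FALSE]
  data.frame(
    chrom = i$chrom, pos = i$sa_pos, strand = i$strand, kind = "SA",
    intron_length = i$length,
    length_class = if (nrow(i)) intron_length_class(i$length) else character(0),
    snoRNA_hosting = i$snoRNA_hosting,
    gene_id = i$gene_id, intron_id = i$intron_id,
    stringsAsFactors = FALSE
  )
}
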