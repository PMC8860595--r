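# 3' end cluster calling and per-library quantification.  Proximal 3' end
# positions are aggregated into clusters on the pooled signal of all raw
# libraries: positions whose pooled count reaches a seed threshold are
# single-linkage merged along each strand when separated by at most
# `max_gap` nucleotides.

#' Call 3' end clusters from pooled raw tracks
#'
#' @param tracks List of raw `end_track` objects sharing chromosome naming.
#' @param min_pos_count Seed threshold: a position enters clustering when its
#'   pooled count across libraries is `>= min_pos_count`; default 3.
#' @param max_gap Seeds on the same chromosome/strand separated by
#'   `<= max_gap` nt are merged; default 25.
#' @return data.frame with columns `cluster_id`, `chrom`, `start`, `end`
#'   (half-open span `[min seed, max seed + 1)`), `strand`, `summit`
#'   (position of maximal pooled signal; 5'-most on ties), `pooled_count`.
#'   May have zero rows.
#' @export
call_clusters <- function(tracks, min_pos_count = 3, max_gap = 25) {
  pooled <- pool_tracks(tracks)
  seeds <- pooled[value >= min_pos_count]
  if (nrow(seeds) == 0) return(empty_clusters())
  data.table::setorder(seeds, chrom, strand, pos)
  brk <- c(TRUE, seeds$chrom[-1] != seeds$chrom[-nrow(seeds)] |
                 seeds$strand[-1] != seeds$strand[-nrow(seeds)] |
                 seeds$pos[-1] - seeds$pos[-nrow(seeds)] > max_gap)
  grp <- cumsum(brk)
  cl <- seeds[, list(chrom = chrom[1], strand = strand[1],
                     start = min(pos), end = max(pos) + 1L,
                     pooled_count = sum(value),
                     summit = pos[which.max(value)]),
              by = list(grp = grp)]
  data.table::setorder(cl, chrom, start, strand)
  out <- data.frame(
    cluster_id = sprintf("cl_%05d", seq_len(nrow(cl))),
    chrom = cl$chrom, start = cl$start, end = cl$end, strand = cl$strand,
    summit = cl$summit, pooled_count = cl$pooled_count,
    stringsAsFactors = FALSE)
  out
}

empty_clusters <- function() {
  data.frame(cluster_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             summit = integer(0), pooled_count = numeric(0))
}

#' Per-library cluster count matrix
#'
#' Sums raw 3' end counts within each cluster interval, strand-matched.
#' Same-strand clusters must be non-overlapping.
#'
#' @param clusters data.frame as returned by [call_clusters()].
#' @param tracks List of raw `end_track` objects.
#' @return Integer matrix cluster x library (dimnames from `cluster_id` and
#'   library ids).
#' @export
count_matrix <- function(clusters, tracks) {
  if (nrow(clusters) == 0)
    return(matrix(0L, 0, length(tracks),
                  dimnames = list(NULL,
                                  vapply(tracks, `[[`, "", "library_id"))))
  cl <- clusters[order(clusters$chrom, clusters$strand, clusters$start), ]
  same <- cl$chrom[-1] == cl$chrom[-nrow(cl)] &
          cl$strand[-1] == cl$strand[-nrow(cl)]
  if (nrow(cl) > 1 && any(same & cl$start[-1] < cl$end[-nrow(cl)]))
    stop("overlapping same-strand clusters")
  m <- vapply(tracks, function(t) sum_in_intervals(t, clusters),
              numeric(nrow(clusters)))
  m <- matrix(m, nrow = nrow(clusters),
              dimnames = list(clusters$cluster_id,
                              vapply(tracks, `[[`, "", "library_id")))
  m
}

CLUSTER_BIOTYPES <- c("PROMPT", "eRNA", "snoRNA", "lncRNA", "protein_coding",
                      "not_annotated")
CLUSTER_FEATURES <- c("SA_snoRNA_host", "SA_regular", "PAS", "ptRNA",
                      "exonic", "intronic")

#' Annotate clusters with biotype and intra-genic feature
#'
#' Biotype is assigned by strand-specific overlap of the cluster interval
#' with gene records, resolved by the priority
#' `PROMPT > eRNA > snoRNA > lncRNA > protein_coding`; clusters hitting
#' nothing are `not_annotated`.  Within protein-coding genes a feature is
#' assigned from the summit position with priority
#' `SA_snoRNA_host > SA_regular > PAS > ptRNA > exonic > intronic`:
#' a summit whose transcription-orientation offset to an SA lies in
#' `[-sa_window, 0]` is "at" that SA; `PAS` means summit within
#' `pas_window` nt of the gene's pA site; `ptRNA` (TSS-proximal premature
#' termination) means summit within `tss_window` nt downstream of the TSS
#' on the sense strand.
#'
#' @param clusters data.frame from [call_clusters()].
#' @param ann An `annotation` object.
#' @param sa_window SA proximity window in nt; default 10.
#' @param pas_window pA-site proximity window in nt; default 10.
#' @param tss_window TSS-proximal window in nt; default 3000.
#' @return data.frame `cluster_id`, `biotype`, `feature` (NA outside
#'   protein-coding genes).
#' @export
annotate_clusters <- function(clusters, ann, sa_window = 10,
                              pas_window = 10, tss_window = 3000) {
  stopifnot(inherits(ann, "annotation"))
  n <- nrow(clusters)
  biotype <- rep("not_annotated", n)
  feature <- rep(NA_character_, n)
  if (n == 0)
    return(data.frame(cluster_id = character(0), biotype = character(0),
                      feature = character(0)))
  hits <- overlap_any(clusters[, c("chrom", "start", "end", "strand")],
                      ann$genes[, c("chrom", "start", "end", "strand")])
  if (nrow(hits) > 0) {
    hit_bio <- ann$genes$biotype[hits$subject]
    prio <- match(hit_bio, CLUSTER_BIOTYPES)
    best <- tapply(seq_len(nrow(hits)), hits$query, function(i) {
      i[which.min(prio[i])]
    })
    qi <- as.integer(names(best))
    biotype[qi] <- hit_bio[unlist(best)]
  }

  pc_idx <- which(biotype == "protein_coding")
  for (ci in pc_idx) {
    feature[ci] <- classify_feature(
      clusters$chrom[ci], clusters$summit[ci], clusters$strand[ci],
      ann, sa_window, pas_window, tss_window)
  }
  data.frame(cluster_id = clusters$cluster_id, biotype = biotype,
             feature = feature, stringsAsFactors = FALSE)
}

# transcription-orientation offset of position p relative to anchor a;
# all arguments recycle
anchor_offset <- function(p, a, strand) {
  ifelse(strand == "+", 1, -1) * (p - a)
}

classify_feature <- function(chrom, summit, strand, ann,
                             sa_window, pas_window, tss_window) {
  introns <- ann$introns
  ii <- which(introns$chrom == chrom & introns$strand == strand)
  if (length(ii)) {
    off <- anchor_offset(summit, introns$sa_pos[ii], strand)
    at_sa <- off >= -sa_window & off <= 0
    if (any(at_sa & introns$snoRNA_hosting[ii])) return("SA_snoRNA_host")
    if (any(at_sa)) return("SA_regular")
  }
  genes <- ann$genes
  gi <- which(genes$chrom == chrom & genes$strand == strand &
              genes$biotype == "protein_coding" &
              summit >= genes$start & summit < genes$end)
  if (length(gi)) {
    if (any(abs(summit - genes$pas[gi]) <= pas_window)) return("PAS")
    tss_off <- anchor_offset(summit, genes$tss[gi], strand)
    if (any(tss_off >= 0 & tss_off <= tss_window)) return("ptRNA")
    ex <- ann$exons
    in_exon <- any(ex$chrom == chrom & ex$strand == strand &
                   ex$gene_id %in% genes$gene_id[gi] &
                   summit >= ex$start & summit < ex$end)
    if (in_exon) return("exonic")
    return("intronic")
  }
  # summit outside the gene body (cluster overlapped only by its edge)
  "intronic"
}
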