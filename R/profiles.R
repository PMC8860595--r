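# Single-nucleotide metagene profiles around oriented anchor points and the
# 3' end trimming readouts (qPCR-style amplicon ratio and an in-silico
# window-ratio index on tracks).

#' Metagene log2 ratio profile around anchors
#'
#' Extracts, per anchor, the oriented window `[-upstream, downstream)` in
#' transcription-orientation offsets (windows of minus-strand anchors are
#' reversed so upstream/downstream follow transcription), aggregates treated
#' and reference coverage across anchors per offset, and returns
#' `log2((T(o) + pc) / (R(o) + pc))`.
#'
#' Default aggregation sums coverage across anchors before the single log
#' ratio (robust to per-anchor zeros); `aggregate = "mean"` instead averages
#' per-anchor log ratios.  Anchors whose window leaves the chromosome are
#' dropped (not clipped) when `chrom_lengths` is supplied; the number
#' dropped is reported as an attribute.
#'
#' @param treated,reference Normalized `end_track` objects sharing the same
#'   size-factor scheme.
#' @param anchors data.frame with columns `chrom`, `pos`, `strand` (e.g.
#'   from [sa_anchors()]).
#' @param upstream,downstream Window extents in nt; defaults 150 and 100.
#' @param pseudocount Added to both sides before the log ratio; default 1.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A `metagene_profile`: data.frame `offset` (`-upstream ..
#'   downstream - 1`, anchor at 0), `value`; attributes `n_anchors`,
#'   `n_dropped`, `treated`, `reference`, `pseudocount`.
#' @export
metagene <- function(treated, reference, anchors, upstream = 150,
                     downstream = 100, pseudocount = 1,
                     aggregate = c("sum", "mean"), chrom_lengths = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(treated, "end_track"), inherits(reference, "end_track"))
  if (!isTRUE(treated$normalized) || !isTRUE(reference$normalized))
    warning("metagene expects normalized tracks")
  offsets <- seq.int(-upstream, downstream - 1L)
  n_dropped <- 0L
  if (!is.null(chrom_lengths)) {
    lo <- ifelse(anchors$strand == "+", anchors$pos - upstream,
                 anchors$pos - (downstream - 1L))
    hi <- ifelse(anchors$strand == "+", anchors$pos + downstream - 1L,
                 anchors$pos + upstream)
    len <- chrom_lengths[anchors$chrom]
    keep <- lo >= 0 & hi < ifelse(is.na(len), Inf, len)
    n_dropped <- sum(!keep)
    anchors <- anchors[keep, , drop = FALSE]
  }
  if (nrow(anchors) == 0) stop("no usable anchors")

  cov <- function(track) anchor_window_matrix(track, anchors, offsets)
  Tm <- cov(treated); Rm <- cov(reference)
  if (aggregate == "sum") {
    v <- log2((colSums(Tm) + pseudocount) / (colSums(Rm) + pseudocount))
  } else {
    v <- colMeans(log2((Tm + pseudocount) / (Rm + pseudocount)))
  }
  out <- data.frame(offset = offsets, value = v)
  attr(out, "n_anchors") <- nrow(anchors)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "treated") <- treated$library_id
  attr(out, "reference") <- reference$library_id
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("metagene_profile", "data.frame")
  out
}

# anchors x offsets coverage matrix in transcription orientation
anchor_window_matrix <- function(track, anchors, offsets) {
  dt <- track$counts
  m <- matrix(0, nrow(anchors), length(offsets))
  if (nrow(dt) == 0) return(m)
  sign <- ifelse(anchors$strand == "+", 1L, -1L)
  q <- data.table::data.table(
    chrom = rep(anchors$chrom, each = length(offsets)),
    strand = rep(anchors$strand, each = length(offsets)),
    pos = rep(anchors$pos, each = length(offsets)) +
      rep(sign, each = length(offsets)) * rep(offsets, nrow(anchors)))
  vals <- dt[q, on = c("chrom", "strand", "pos")]$value
  vals[is.na(vals)] <- 0
  matrix(vals, nrow = nrow(anchors), ncol = length(offsets), byrow = TRUE)
}

#' qPCR relative quantity (delta-Ct)
#'
#' `2^-(ct_target - ct_reference)`: quantity of a target amplicon relative
#' to a reference transcript's amplicon.
#'
#' @param ct_target,ct_reference Finite Ct values.
#' @return Relative quantity.
#' @export
qpcr_normalize <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' Trimming factor from amplicon quantities
#'
#' Ratio of SA-distal to SA-proximal reference-normalized amplicon
#' quantities.  Values > 1 indicate 3'-trimmed species retaining the distal
#' but not the proximal region; a common fold-change of both amplicons
#' (full-length stabilization) cancels, leaving the factor at 1.
#'
#' @param distal_q,proximal_q Positive relative quantities.
#' @return `distal_q / proximal_q`.
#' @export
trimming_factor <- function(distal_q, proximal_q) {
  if (any(proximal_q == 0)) stop("proximal quantity must be non-zero")
  if (any(distal_q < 0) || any(proximal_q < 0))
    stop("quantities must be positive")
  distal_q / proximal_q
}

#' In-silico trimming index at SA anchors
#'
#' Ratio of pseudocounted 3' end signal summed (across anchors) in a
#' SA-distal window to that in a SA-proximal window, both given as
#' inclusive transcription-orientation offset ranges relative to the SA.
#' Nonprocessive trimming scatters 3' ends into the distal window and
#' drives the index above 1; intact SA-proximal 3' end peaks keep it
#' below 1.
#'
#' @param track Normalized `end_track`.
#' @param anchors SA anchor data.frame (`chrom`, `pos`, `strand`).
#' @param proximal,distal Integer length-2 vectors `c(from, to)` of
#'   inclusive offsets; defaults `c(-10, 0)` and `c(-150, -20)`.  Windows
#'   must not overlap.
#' @param pseudocount Added to both sums; default 1.
#' @return Numeric scalar index.
#' @export
insilico_trimming_index <- function(track, anchors, proximal = c(-10, 0),
                                    distal = c(-150, -20), pseudocount = 1) {
  stopifnot(length(proximal) == 2, length(distal) == 2)
  if (max(distal) >= min(proximal) && max(proximal) >= min(distal))
    stop("proximal and distal windows overlap")
  wsum <- function(win) {
    offs <- seq.int(win[1], win[2])
    sum(anchor_window_matrix(track, anchors, offs))
  }
  (wsum(distal) + pseudocount) / (wsum(proximal) + pseudocount)
}
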