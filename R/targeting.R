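# The depletion-sensitivity statistic, the RNAi x AID intersection
# classification into mutually exclusive NEXT and PAXT targeting classes,
# and composition / intron-length stratification summaries.

#' Depletion sensitivity statistic
#'
#' `sensitivity = (treated - ctrl) / max(ctrl, treated, 1)` on
#' replicate-averaged normalized signal.  Bounded in `[-1, 1]`: signal
#' exclusive to the depletion sample gives 1, exclusive to the control -1,
#' equal signal 0.  The unit floor in the denominator keeps sub-unit
#' signals from reaching the bounds.
#'
#' @param treated,ctrl Non-negative numeric vectors (recycled).
#' @return Numeric vector of sensitivity values.
#' @examples
#' sensitivity(37, 0)    # 1
#' sensitivity(58, 58)   # 0
#' sensitivity(0, 12)    # -1
#' @export
sensitivity <- function(treated, ctrl) {
  if (any(treated < 0, na.rm = TRUE) || any(ctrl < 0, na.rm = TRUE))
    stop("sensitivity inputs must be non-negative")
  (treated - ctrl) / pmax(ctrl, treated, 1)
}

#' Sensitivity matrix over contrasts
#'
#' Averages normalized cluster counts over each contrast's replicate groups
#' (arithmetic mean), then applies [sensitivity()] per cluster.
#'
#' @param norm_counts Normalized count matrix cluster x library.
#' @param contrasts Named list; each element a list with character vectors
#'   `treated` and `ref` of library ids (non-empty, present in the matrix).
#' @return Numeric matrix cluster x contrast, all entries in `[-1, 1]`.
#' @export
sensitivity_matrix <- function(norm_counts, contrasts) {
  stopifnot(length(contrasts) > 0)
  cols <- lapply(contrasts, function(ct) {
    if (length(ct$treated) == 0 || length(ct$ref) == 0)
      stop("contrast with empty group")
    missing <- setdiff(c(ct$treated, ct$ref), colnames(norm_counts))
    if (length(missing))
      stop("libraries missing from matrix: ", paste(missing, collapse = ", "))
    tr <- rowMeans(norm_counts[, ct$treated, drop = FALSE])
    rf <- rowMeans(norm_counts[, ct$ref, drop = FALSE])
    sensitivity(tr, rf)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rownames(norm_counts), names(contrasts))
  m
}

#' Classify clusters into mutually exclusive NEXT/PAXT targeting classes
#'
#' In `"RNAi+AID"` mode, candidates are the intersections of the RNAi and
#' 6 h AID upregulated sets per pathway (`NEXT`: ZCCHC8 depletions; `PAXT`:
#' ZFC3H1 depletions); mutual exclusion is then applied so a cluster
#' upregulated in both pathways belongs to neither class.  In `"RNAi"` mode
#' the same exclusion is applied to the RNAi sets alone.  Callers wishing to
#' combine pA+ and pA+/- calls should union them per method first (see
#' [union_pa_modes()]).
#'
#' @param up_rnai_next,up_aid_next,up_rnai_paxt,up_aid_paxt Character
#'   vectors of upregulated cluster ids ([call_upregulated()] outputs).
#' @param mode `"RNAi+AID"` (default) or `"RNAi"`.
#' @return List with character vectors `NEXT` and `PAXT` (disjoint) and the
#'   pre-exclusion `NEXT_candidates`/`PAXT_candidates`.
#' @export
classify_targets <- function(up_rnai_next, up_aid_next,
                             up_rnai_paxt, up_aid_paxt,
                             mode = c("RNAi+AID", "RNAi")) {
  mode <- match.arg(mode)
  if (mode == "RNAi+AID") {
    next_cand <- intersect(up_rnai_next, up_aid_next)
    paxt_cand <- intersect(up_rnai_paxt, up_aid_paxt)
  } else {
    next_cand <- unique(up_rnai_next)
    paxt_cand <- unique(up_rnai_paxt)
  }
  list(NEXT = setdiff(next_cand, paxt_cand),
       PAXT = setdiff(paxt_cand, next_cand),
       NEXT_candidates = next_cand, PAXT_candidates = paxt_cand)
}

#' Union upregulated calls across pA modes
#'
#' @param ... Character vectors of cluster ids (e.g. the pA+ and pA+/- calls
#'   of one method).
#' @return Their union.
#' @export
union_pa_modes <- function(...) unique(unlist(list(...)))

#' Composition of a targeting class
#'
#' Percentage of class members per biotype or feature label; `NA` labels are
#' reported as `not_annotated`.
#'
#' @param members Character vector of cluster ids.
#' @param cluster_annotation data.frame from [annotate_clusters()].
#' @param level `"biotype"` or `"feature"`.
#' @return Named numeric vector of percentages summing to 100 (empty, with a
#'   warning, for an empty class).
#' @export
composition <- function(members, cluster_annotation,
                        level = c("biotype", "feature")) {
  level <- match.arg(level)
  if (length(members) == 0) {
    warning("empty targeting class")
    return(setNames(numeric(0), character(0)))
  }
  lab <- cluster_annotation[[level]][
    match(members, cluster_annotation$cluster_id)]
  lab[is.na(lab)] <- "not_annotated"
  tab <- table(lab)
  setNames(100 * as.numeric(tab) / length(members), names(tab))
}

#' Intron length classes
#'
#' `short`: length < 700 nt; `medium`: 700-4000 nt inclusive; `long`:
#' length > 4000 nt.
#'
#' @param length_nt Positive integer vector of intron lengths.
#' @return Character vector of class labels.
#' @export
intron_length_class <- function(length_nt) {
  if (any(length_nt <= 0)) stop("intron length must be positive")
  ifelse(length_nt < 700, "short",
         ifelse(length_nt <= 4000, "medium", "long"))
}

#' SA-site overlap fractions per intron length class
#'
#' For each condition and length class, the fraction of SA sites having at
#' least one upregulated cluster whose summit lies within `sa_window` nt
#' upstream of the SA (transcription-orientation offset in
#' `[-sa_window, 0]`).  The denominator is either all anchors in the
#' stratum (`"all"`) or only anchors covered by any called cluster in the
#' window (`"expressed"`).
#'
#' @param anchors SA anchor data.frame from [sa_anchors()].
#' @param up_sets Named list of character vectors of upregulated cluster ids
#'   (one per condition).
#' @param clusters Cluster data.frame from [call_clusters()].
#' @param sa_window Window in nt; default 10.
#' @param denominator `"all"` or `"expressed"`.
#' @return data.frame `condition`, `length_class`, `n_sa`, `n_up`,
#'   `fraction` (in percent; `NA` for an empty stratum).
#' @export
sa_overlap_fraction <- function(anchors, up_sets, clusters, sa_window = 10,
                                denominator = c("all", "expressed")) {
  denominator <- match.arg(denominator)
  # cluster x anchor proximity by summit offset
  near <- function(cl_idx) {
    off <- anchor_offset(clusters$summit[cl_idx], anchors$pos,
                         anchors$strand)
    same <- clusters$chrom[cl_idx] == anchors$chrom &
      clusters$strand[cl_idx] == anchors$strand
    same & off >= -sa_window & off <= 0
  }
  covered_any <- rep(FALSE, nrow(anchors))
  hit <- matrix(FALSE, nrow(anchors), length(up_sets),
                dimnames = list(NULL, names(up_sets)))
  for (ci in seq_len(nrow(clusters))) {
    nb <- near(ci)
    if (!any(nb)) next
    covered_any <- covered_any | nb
    for (cond in names(up_sets)) {
      if (clusters$cluster_id[ci] %in% up_sets[[cond]])
        hit[nb, cond] <- TRUE
    }
  }
  out <- list()
  classes <- c("short", "medium", "long")
  for (cond in names(up_sets)) {
    for (lc in classes) {
      sel <- anchors$length_class == lc
      if (denominator == "expressed") sel <- sel & covered_any
      n_sa <- sum(sel)
      n_up <- sum(hit[sel, cond])
      out[[paste(cond, lc)]] <- data.frame(
        condition = cond, length_class = lc, n_sa = n_sa, n_up = n_up,
        fraction = if (n_sa > 0) 100 * n_up / n_sa else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}
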