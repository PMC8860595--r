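# End-to-end orchestration: simulate (or load) tracks, normalize, call and
# annotate clusters, test differential expression, score sensitivity,
# classify NEXT/PAXT targets, stratify SA overlap, profile metagenes and
# trimming, and run PCA.  Every written table carries a header naming the
# producing stage and a hash of the run configuration.

#' Build contrast groups from a design sheet
#'
#' AID contrasts compare each depleted time point to the same line's 0 h
#' libraries of the same pA mode; RNAi contrasts compare each target to the
#' control knockdown of the same pA mode.
#'
#' @param design Library sheet (see [default_design()]).
#' @return Named list of `list(treated =, ref =, target =, method =,
#'   timepoint_h =, pA_mode =)` entries.
#' @export
build_contrasts <- function(design) {
  out <- list()
  mode_tag <- function(m) ifelse(m == "pA+", "pAplus", "pAall")
  aid <- design[design$method == "AID", ]
  for (tg in unique(aid$target)) for (m in unique(aid$pA_mode)) {
    ref <- aid$library_id[aid$target == tg & aid$pA_mode == m &
                          aid$timepoint_h == 0]
    for (t in setdiff(sort(unique(aid$timepoint_h[aid$target == tg])), 0)) {
      tr <- aid$library_id[aid$target == tg & aid$pA_mode == m &
                           aid$timepoint_h == t]
      if (length(tr) == 0 || length(ref) == 0) next
      nm <- sprintf("AID_%s_%gh_%s", tg, t, mode_tag(m))
      out[[nm]] <- list(treated = tr, ref = ref, target = tg,
                        method = "AID", timepoint_h = t, pA_mode = m)
    }
  }
  rn <- design[design$method == "RNAi", ]
  for (tg in setdiff(unique(rn$target), "ctrl")) for (m in unique(rn$pA_mode)) {
    tr <- rn$library_id[rn$target == tg & rn$pA_mode == m]
    ref <- rn$library_id[rn$target == "ctrl" & rn$pA_mode == m]
    if (length(tr) == 0 || length(ref) == 0) next
    nm <- sprintf("RNAi_%s_%s", tg, mode_tag(m))
    out[[nm]] <- list(treated = tr, ref = ref, target = tg,
                      method = "RNAi", timepoint_h = NA, pA_mode = m)
  }
  out
}

#' Differential expression for one contrast
#'
#' Subsets the count matrix to the contrast's libraries and runs
#' [nb_wald()]; RNAi contrasts include the batch covariate when the design
#' carries more than one batch.
#'
#' @param counts Raw cluster count matrix.
#' @param sf Named size factors.
#' @param design Library sheet.
#' @param contrast One element of [build_contrasts()].
#' @return [nb_wald()] result data.frame.
#' @export
de_contrast <- function(counts, sf, design, contrast) {
  libs <- c(contrast$ref, contrast$treated)
  cond <- factor(c(rep("ref", length(contrast$ref)),
                   rep("treated", length(contrast$treated))),
                 levels = c("ref", "treated"))
  batch <- design$batch[match(libs, design$library_id)]
  if (all(is.na(batch)) || length(unique(batch[!is.na(batch)])) < 2)
    batch <- NULL
  nb_wald(counts[, libs, drop = FALSE], sf[libs], cond, batch = batch)
}

#' Pipeline run configuration
#'
#' @param sim [sim_config()] for the synthetic inputs.
#' @param design Library sheet; default [default_design()].
#' @param outdir Output directory (created); `NULL` for no file output.
#' @param min_reads,pseudocount Normalization parameters.
#' @param min_pos_count,max_gap Cluster-caller parameters.
#' @param lfc_min,padj_max Upregulation thresholds.
#' @param n_top PCA cluster count.
#' @param sa_window SA proximity window (nt).
#' @param metagene_upstream,metagene_downstream Metagene window (nt).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), design = default_design(),
                            outdir = NULL, min_reads = 100, pseudocount = 1,
                            min_pos_count = 3, max_gap = 25, lfc_min = 1,
                            padj_max = 0.1, n_top = 2000, sa_window = 10,
                            metagene_upstream = 150,
                            metagene_downstream = 100) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  # hash the scientific parameters only: output location is not a parameter
  writeLines(deparse(cfg[setdiff(names(cfg), c("design", "outdir"))]), f)
  unname(tools::md5sum(f))
}

write_stage_tsv <- function(df, path, stage, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s | params: %s", stage, hash), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> normalize -> cluster -> annotate -> differential
#' expression -> sensitivity -> classification -> composition -> SA
#' stratification -> metagene/trimming -> PCA, returning all intermediate
#' objects and (when `outdir` is set) writing stage-stamped TSVs.
#' Deterministic given the configuration.
#'
#' @param cfg A `pipeline_config`.
#' @return (Invisibly) a list with `truth`, `design`, `size_factors`,
#'   `clusters`, `cluster_annotation`, `counts`, `de` (per contrast),
#'   `upregulated` (per contrast), `classes`, `composition_biotype`,
#'   `sensitivity`, `sa_overlap`, `metagene`, `trimming`, `pca`,
#'   `truth_match` (planted cluster -> called cluster map).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(cfg)
  design <- cfg$design
  ann <- simulate_annotation(cfg$sim)
  sim <- simulate_tracks(ann, cfg$sim, design)
  tracks <- sim$tracks

  lem <- last_exon_matrix(tracks, ann)
  sf <- size_factors(filter_expressed(lem, cfg$min_reads), cfg$pseudocount)

  clusters <- call_clusters(tracks, cfg$min_pos_count, cfg$max_gap)
  cl_ann <- annotate_clusters(clusters, ann, sa_window = cfg$sa_window)
  counts <- count_matrix(clusters, tracks)
  norm_counts <- normalize_counts(counts, sf)

  contrasts <- build_contrasts(design)
  de <- lapply(contrasts, function(ct) de_contrast(counts, sf, design, ct))
  up <- lapply(de, call_upregulated, lfc_min = cfg$lfc_min,
               padj_max = cfg$padj_max)

  sens <- sensitivity_matrix(norm_counts, contrasts)

  classes <- NULL
  need <- c("RNAi_ZCCHC8", "AID_ZCCHC8_6h", "RNAi_ZFC3H1", "AID_ZFC3H1_6h")
  have <- vapply(need, function(p) any(startsWith(names(up), p)), logical(1))
  if (all(have)) {
    u <- function(p) union_pa_modes(unlist(up[startsWith(names(up), p)]))
    classes <- classify_targets(u("RNAi_ZCCHC8"), u("AID_ZCCHC8_6h"),
                                u("RNAi_ZFC3H1"), u("AID_ZFC3H1_6h"))
  }
  comp <- if (!is.null(classes) && length(classes$NEXT))
    composition(classes$NEXT, cl_ann, "biotype") else NULL

  anchors_reg <- sa_anchors(ann, hosting = FALSE)
  sa_sets <- list()
  for (nm in names(up))
    if (startsWith(nm, "RNAi_ZCCHC8") || startsWith(nm, "AID_ZCCHC8"))
      sa_sets[[nm]] <- up[[nm]]
  sa_tab <- if (length(sa_sets))
    sa_overlap_fraction(anchors_reg, sa_sets, clusters, cfg$sa_window)
    else NULL

  # metagene + trimming at snoRNA-hosting SA anchors for 6 h depletions
  anchors_sno <- sa_anchors(ann, hosting = TRUE)
  prof <- NULL; trim <- NULL
  mg_pair <- function(tg) {
    tr_ids <- design$library_id[design$method == "AID" &
      design$target == tg & design$timepoint_h == 6 &
      design$pA_mode == "pA+/-"]
    rf_ids <- design$library_id[design$method == "AID" &
      design$target == tg & design$timepoint_h == 0 &
      design$pA_mode == "pA+/-"]
    if (length(tr_ids) == 0 || length(rf_ids) == 0) return(NULL)
    list(tr = normalize_counts(tracks[[tr_ids[1]]], sf),
         rf = normalize_counts(tracks[[rf_ids[1]]], sf))
  }
  if (nrow(anchors_sno) > 0) {
    pz <- mg_pair("ZCCHC8"); pe <- mg_pair("EXOSC3")
    if (!is.null(pz)) {
      prof <- metagene(pz$tr, pz$rf, anchors_sno,
                       cfg$metagene_upstream, cfg$metagene_downstream,
                       chrom_lengths = ann$seqlengths)
      trim <- c(ZCCHC8_6h = insilico_trimming_index(pz$tr, anchors_sno))
    }
    if (!is.null(pe))
      trim <- c(trim,
                EXOSC3_6h = insilico_trimming_index(pe$tr, anchors_sno))
  }

  pca <- if (ncol(counts) >= 3 && nrow(counts) >= 2)
    pca_top_variance(counts, sf, cfg$n_top) else NULL

  truth_match <- match_truth_clusters(sim$truth, clusters)

  res <- list(config_hash = hash, truth = sim$truth, design = design,
              annotation = ann, size_factors = sf, clusters = clusters,
              cluster_annotation = cl_ann, counts = counts,
              norm_counts = norm_counts, contrasts = contrasts, de = de,
              upregulated = up, classes = classes,
              composition_biotype = comp, sensitivity = sens,
              sa_overlap = sa_tab, metagene = prof, trimming = trim,
              pca = pca, truth_match = truth_match)

  if (!is.null(cfg$outdir)) write_pipeline_outputs(res, cfg, hash)
  invisible(res)
}

#' Match planted truth clusters to called clusters
#'
#' Strand-specific overlap of planted footprints with called cluster
#' intervals, reporting the Jaccard index of each matched pair.
#'
#' @param truth Truth table.
#' @param clusters Called clusters.
#' @return data.frame `truth_id`, `cluster_id` (NA when unrecovered),
#'   `jaccard`.
#' @export
match_truth_clusters <- function(truth, clusters) {
  res <- data.frame(truth_id = truth$cluster_id,
                    cluster_id = NA_character_, jaccard = 0,
                    stringsAsFactors = FALSE)
  if (nrow(clusters) == 0 || nrow(truth) == 0) return(res)
  hits <- overlap_any(truth[, c("chrom", "start", "end", "strand")],
                      clusters[, c("chrom", "start", "end", "strand")])
  for (k in seq_len(nrow(hits))) {
    ti <- hits$query[k]; ci <- hits$subject[k]
    inter <- min(truth$end[ti], clusters$end[ci]) -
      max(truth$start[ti], clusters$start[ci])
    uni <- max(truth$end[ti], clusters$end[ci]) -
      min(truth$start[ti], clusters$start[ci])
    j <- inter / uni
    if (j > res$jaccard[ti]) {
      res$jaccard[ti] <- j
      res$cluster_id[ti] <- clusters$cluster_id[ci]
    }
  }
  res
}

write_pipeline_outputs <- function(res, cfg, hash) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(df, name, stage)
    write_stage_tsv(df, file.path(cfg$outdir, name), stage, hash)
  out(data.frame(library_id = names(res$size_factors),
                 size_factor = unname(res$size_factors)),
      "size_factors.tsv", "normalize")
  out(res$clusters, "clusters.tsv", "cluster")
  out(res$cluster_annotation, "cluster_annotation.tsv", "annotate")
  out(data.frame(cluster_id = rownames(res$counts), res$counts,
                 check.names = FALSE), "cluster_counts.tsv", "cluster")
  for (nm in names(res$de))
    out(res$de[[nm]], paste0("de_", nm, ".tsv"), "diffexp")
  out(data.frame(cluster_id = rownames(res$sensitivity), res$sensitivity,
                 check.names = FALSE), "sensitivity.tsv", "sensitivity")
  if (!is.null(res$classes))
    out(data.frame(
      cluster_id = c(res$classes$NEXT, res$classes$PAXT),
      class = rep(c("NEXT", "PAXT"),
                  c(length(res$classes$NEXT), length(res$classes$PAXT)))),
      "target_classes.tsv", "classify")
  if (!is.null(res$sa_overlap))
    out(res$sa_overlap, "sa_overlap.tsv", "sa-overlap")
  if (!is.null(res$metagene))
    out(as.data.frame(res$metagene), "metagene_sno_sa.tsv", "metagene")
  if (!is.null(res$trimming))
    out(data.frame(condition = names(res$trimming),
                   trimming_index = unname(res$trimming)),
        "trimming_index.tsv", "trimming")
  if (!is.null(res$pca)) out(res$pca, "pca.tsv", "pca")
  out(res$truth, "truth.tsv", "simulate")
  manifest <- data.frame(
    key = c("package_version", "config_hash", "n_libraries", "n_clusters"),
    value = c(as.character(utils::packageVersion("exosens")), hash,
              nrow(res$design), nrow(res$clusters)))
  out(manifest, "manifest.tsv", "run-all")
  invisible(NULL)
}
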