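# Synthetic-data generator.  Plants the statistical structure the analysis
# assumes: an annotation with PROMPT/eRNA/lncRNA loci and multi-intron
# protein-coding genes (some introns hosting snoRNAs), per-library pA+ and
# pA+/- 3' end tracks with negative-binomial cluster counts, pathway- and
# kinetics-specific depletion effects, pA- -> pA+ signal handover under
# NEXT loss, RNAi-only intron-length-scaled effects at regular splice
# acceptors, and a heterogeneous trimming smear upstream of SA sites in
# core-exosome depletions.  Everything is deterministic given the seed.

#' Simulation configuration
#'
#' Defaults define the study conditions every downstream test assumes.
#'
#' @param seed Master seed; all generator randomness derives from it.
#' @param n_genes Number of multi-intron protein-coding genes.
#' @param n_lncrna,n_ernas Numbers of lncRNA genes and eRNA loci.
#' @param introns_per_gene Integer range `c(min, max)`.
#' @param exon_len Exon length range in nt.
#' @param intron_mix Probabilities of the short (<700 nt), medium
#'   (700-4000 nt) and long (>4000 nt) intron length classes; must sum to 1.
#' @param frac_sno_host Probability that an eligible (medium/long) intron
#'   hosts a snoRNA.
#' @param effect_size Planted pathway effect in log2 units; default 2.
#' @param alpha NB dispersion (variance = mu + alpha mu^2); default 0.05.
#' @param base_mu Named baseline mean counts for `PAS`, `SA` and `other`
#'   cluster classes; drawn log-normal around these.
#' @param base_sdlog Log-normal sdlog of baseline means; default 0.6.
#' @param pathway_probs Sampling probabilities of `NEXT`, `PAXT`, `both`,
#'   `none` pathways for noncoding/ptRNA clusters.
#' @param rnai_indirect_slope Extra log2FC at regular-intron SAs under
#'   long-term (RNAi) NEXT depletion, per length class; default
#'   `c(short = 0, medium = 0.7, long = 1.5)`.
#' @param smear_center,smear_sd Trimming smear: Gaussian of 3' ends centered
#'   `smear_center` nt upstream of the SA with sd `smear_sd` nt, applied in
#'   EXOSC3 depletion conditions only; defaults 50 and 30.
#' @param smear_frac Fraction of a trimming target's signal redistributed
#'   into the smear; default 0.8.
#' @param handover_fraction Fraction of NEXT clusters whose nonadenylated
#'   signal is handed over to the adenylated fraction under NEXT loss.
#' @param handover_share pA+ share of a handover cluster's signal under
#'   NEXT depletion; default 0.7.
#' @param pa_base_share pA+ share of predominantly nonadenylated species;
#'   default 0.15.
#' @param batch_sd sdlog2 of per-cluster multiplicative batch offsets for
#'   non-reference batches (RNAi libraries); default 0.2.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 40, n_lncrna = 8, n_ernas = 15,
                       introns_per_gene = c(3, 6), exon_len = c(150, 400),
                       intron_mix = c(short = 1/3, medium = 1/3, long = 1/3),
                       frac_sno_host = 0.25, effect_size = 2, alpha = 0.05,
                       base_mu = c(PAS = 600, SA = 120, other = 150),
                       base_sdlog = 0.6,
                       pathway_probs = c(NEXT = 0.4, PAXT = 0.3,
                                         both = 0.15, none = 0.15),
                       rnai_indirect_slope = c(short = 0, medium = 0.7,
                                               long = 1.5),
                       smear_center = 50, smear_sd = 30, smear_frac = 0.8,
                       handover_fraction = 0.3, handover_share = 0.7,
                       pa_base_share = 0.15, batch_sd = 0.2) {
  stopifnot(abs(sum(intron_mix) - 1) < 1e-8, all(intron_mix >= 0),
            alpha >= 0, effect_size >= 0, all(base_mu > 0),
            smear_sd > 0, smear_frac >= 0, smear_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a transcriptome annotation
#'
#' Lays out, on one synthetic chromosome, multi-intron protein-coding genes
#' (alternating strands) with antisense PROMPT regions upstream of each TSS,
#' intron-hosted snoRNAs (placed so that their 3' ends sit 180-260 nt
#' upstream of the host SA), lncRNA genes and intergenic eRNA loci.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return An `annotation` object (with `seqlengths`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_annotation_impl(cfg))
}

simulate_annotation_impl <- function(cfg) {
  chrom <- "chrS1"
  cursor <- 10000L
  rows <- list()
  add <- function(gid, bio, st, starts, ends) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gid, chrom = chrom, start = as.integer(starts),
      end = as.integer(ends), strand = st, biotype = bio,
      stringsAsFactors = FALSE)
  }
  len_classes <- names(cfg$intron_mix)
  draw_intron_len <- function() {
    cls <- sample(len_classes, 1, prob = cfg$intron_mix)
    switch(cls,
           short = sample(150:699, 1),
           medium = sample(700:4000, 1),
           long = sample(4001:10000, 1))
  }
  for (i in seq_len(cfg$n_genes)) {
    st <- if (i %% 2 == 1) "+" else "-"
    gid <- sprintf("gene_%03d", i)
    n_int <- sample(cfg$introns_per_gene[1]:cfg$introns_per_gene[2], 1)
    ex_len <- sample(cfg$exon_len[1]:cfg$exon_len[2], n_int + 1,
                     replace = TRUE)
    in_len <- replicate(n_int, draw_intron_len())
    # walk genomic left -> right; exon order equals transcription order on
    # "+" and is reversed on "-"
    starts <- integer(n_int + 1); ends <- integer(n_int + 1)
    p <- cursor + 2500L   # leave room for the PROMPT region
    for (k in seq_len(n_int + 1)) {
      starts[k] <- p; ends[k] <- p + ex_len[k]
      p <- ends[k] + if (k <= n_int) in_len[k] else 0L
    }
    add(gid, "protein_coding", st, starts, ends)
    tss <- if (st == "+") starts[1] else ends[n_int + 1] - 1L
    # antisense PROMPT upstream of the TSS
    if (st == "+") {
      add(paste0("pro_", gid), "PROMPT", "-", tss - 2200L, tss - 200L)
    } else {
      add(paste0("pro_", gid), "PROMPT", "+", tss + 201L, tss + 2201L)
    }
    # intron-hosted snoRNAs
    gl_starts <- ends[-(n_int + 1)]; gl_ends <- starts[-1]  # genomic introns
    for (k in seq_len(n_int)) {
      ilen <- gl_ends[k] - gl_starts[k]
      if (ilen < 600) next
      if (runif(1) >= cfg$frac_sno_host) next
      sno_len <- sample(80:140, 1)
      gap <- sample(180:260, 1)
      if (ilen <= sno_len + gap + 30) next
      if (st == "+") {
        s3 <- gl_ends[k] - gap           # sno 3' end (exclusive bound)
        add(sprintf("sno_%s_%d", gid, k), "snoRNA", st, s3 - sno_len, s3)
      } else {
        s3 <- gl_starts[k] - 1L + gap    # sno 3' end genomic position
        add(sprintf("sno_%s_%d", gid, k), "snoRNA", st, s3, s3 + sno_len)
      }
    }
    cursor <- max(ends) + sample(3000:5000, 1)
  }
  for (i in seq_len(cfg$n_lncrna)) {
    st <- if (i %% 2 == 1) "-" else "+"
    gid <- sprintf("lnc_%03d", i)
    e1 <- sample(300:600, 1); il <- sample(400:1500, 1); e2 <- sample(300:600, 1)
    add(gid, "lncRNA", st, c(cursor, cursor + e1 + il),
        c(cursor + e1, cursor + e1 + il + e2))
    cursor <- cursor + e1 + il + e2 + sample(3000:5000, 1)
  }
  for (i in seq_len(cfg$n_ernas)) {
    st <- if (i %% 2 == 1) "+" else "-"
    len <- sample(800:1500, 1)
    add(sprintf("eRNA_%03d", i), "eRNA", st, cursor, cursor + len)
    cursor <- cursor + len + sample(2500:4000, 1)
  }
  exons <- do.call(rbind, rows)
  seqlen <- stats::setNames(max(exons$end) + 10000L, chrom)
  derive_annotation(exons, seqlengths = seqlen)
}

#' Default library design sheet
#'
#' AID arm: duplicate pA+ and pA+/- libraries of each tagged line at 0, 2
#' and 6 h IAA (the 0 h libraries are the contrast references).  RNAi arm:
#' triplicate libraries per depletion target plus a control knockdown,
#' with replicates alternating between two library-preparation batches.
#'
#' @param targets Depletion targets; default ZCCHC8, ZFC3H1, EXOSC3.
#' @param aid_timepoints IAA exposure times in h; default `c(0, 2, 6)`.
#' @param aid_replicates,rnai_replicates Replicates per condition.
#' @param pa_modes Library types; default both `"pA+"` and `"pA+/-"`.
#' @param rnai Include the RNAi arm; default `TRUE`.
#' @param batches Batch labels cycled over RNAi replicates.
#' @return data.frame with columns `library_id`, `target`, `method`,
#'   `timepoint_h`, `pA_mode`, `replicate`, `batch`, `depth`.
#' @export
default_design <- function(targets = c("ZCCHC8", "ZFC3H1", "EXOSC3"),
                           aid_timepoints = c(0, 2, 6),
                           aid_replicates = 2, rnai_replicates = 3,
                           pa_modes = c("pA+", "pA+/-"), rnai = TRUE,
                           batches = c("b1", "b2")) {
  rows <- list()
  mode_tag <- function(m) ifelse(m == "pA+", "pAplus", "pAall")
  for (tg in targets) for (t in aid_timepoints) for (m in pa_modes)
    for (r in seq_len(aid_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        library_id = sprintf("AID_%s_%dh_%s_r%d", tg, t, mode_tag(m), r),
        target = tg, method = "AID", timepoint_h = t, pA_mode = m,
        replicate = r, batch = NA_character_, depth = 1,
        stringsAsFactors = FALSE)
    }
  if (rnai) {
    for (tg in c("ctrl", targets)) for (m in pa_modes)
      for (r in seq_len(rnai_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          library_id = sprintf("RNAi_%s_%s_r%d", tg, mode_tag(m), r),
          target = tg, method = "RNAi", timepoint_h = NA_real_, pA_mode = m,
          replicate = r, batch = batches[(r - 1) %% length(batches) + 1],
          depth = 1, stringsAsFactors = FALSE)
      }
  }
  out <- do.call(rbind, rows)
  validate_design(out)
  out
}

validate_design <- function(design) {
  need <- c("library_id", "target", "method", "timepoint_h", "pA_mode",
            "replicate")
  stopifnot(all(need %in% names(design)))
  if (anyDuplicated(design$library_id)) stop("duplicate library_id in design")
  for (tg in setdiff(unique(design$target[design$method == "AID"]), "ctrl")) {
    sub <- design[design$method == "AID" & design$target == tg, ]
    if (any(sub$timepoint_h > 0) && !any(sub$timepoint_h == 0))
      stop("AID design for ", tg, " lacks its 0 h reference libraries")
  }
  if (any(design$method == "RNAi") &&
      any(design$method == "RNAi" & design$target != "ctrl") &&
      !any(design$method == "RNAi" & design$target == "ctrl"))
    stop("RNAi design lacks control libraries")
  invisible(design)
}

# --- planted truth -------------------------------------------------------

build_truth <- function(ann, cfg) {
  g <- ann$genes
  rows <- list()
  add <- function(feature, chrom, strand, focal, pathway, base0,
                  intron_id = NA_character_, intron_length = NA_integer_,
                  trimming = FALSE, sno_gap = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, chrom = chrom, strand = strand,
      focal = as.integer(focal), pathway = pathway, base0 = base0,
      intron_id = intron_id, intron_length = intron_length,
      trimming_target = trimming, sno_gap = sno_gap,
      stringsAsFactors = FALSE)
  }
  draw_pathway <- function() sample(names(cfg$pathway_probs), 1,
                                    prob = cfg$pathway_probs)
  for (i in seq_len(nrow(g))) {
    bio <- g$biotype[i]
    if (bio %in% c("PROMPT", "eRNA", "lncRNA")) {
      add(bio, g$chrom[i], g$strand[i], g$pas[i], draw_pathway(),
          cfg$base_mu[["other"]])
    } else if (bio == "protein_coding") {
      add("PAS", g$chrom[i], g$strand[i], g$pas[i], "none",
          cfg$base_mu[["PAS"]])
      # premature-termination 3' end inside the first exon
      ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], ]
      e1 <- if (g$strand[i] == "+") ex[which.min(ex$start), ]
            else ex[which.max(ex$end), ]
      d <- sample(30:(e1$end - e1$start - 25), 1)
      focal <- if (g$strand[i] == "+") e1$start + d else e1$end - 1L - d
      add("ptRNA", g$chrom[i], g$strand[i], focal, draw_pathway(),
          cfg$base_mu[["other"]])
    }
  }
  pc_ids <- g$gene_id[g$biotype == "protein_coding"]
  introns <- ann$introns[ann$introns$gene_id %in% pc_ids, , drop = FALSE]
  for (k in seq_len(nrow(introns))) {
    focal <- if (introns$strand[k] == "+") introns$sa_pos[k] - 1L
             else introns$sa_pos[k] + 1L
    if (introns$snoRNA_hosting[k]) {
      gap <- if (introns$strand[k] == "+")
        introns$sa_pos[k] - introns$sno_end[k]
      else introns$sno_start[k] - introns$sa_pos[k]
      add("SA_snoRNA_host", introns$chrom[k], introns$strand[k], focal,
          "NEXT", cfg$base_mu[["SA"]], introns$intron_id[k],
          introns$length[k], trimming = TRUE, sno_gap = as.integer(gap))
    } else {
      add("SA_regular", introns$chrom[k], introns$strand[k], focal,
          "none", cfg$base_mu[["SA"]], introns$intron_id[k],
          introns$length[k])
    }
  }
  truth <- do.call(rbind, rows)
  truth$cluster_id <- sprintf("t_%04d", seq_len(nrow(truth)))
  truth$base_mean <- stats::rlnorm(nrow(truth), log(truth$base0),
                                   cfg$base_sdlog)
  truth$length_class <- NA_character_
  has_len <- !is.na(truth$intron_length)
  truth$length_class[has_len] <-
    intron_length_class(truth$intron_length[has_len])
  truth$kinetic <- ifelse(truth$pathway == "NEXT", "plateau",
                          ifelse(truth$pathway %in% c("PAXT", "both"),
                                 "progressive", NA_character_))
  is_next <- truth$pathway == "NEXT" &
    truth$feature %in% c("PROMPT", "eRNA", "lncRNA", "ptRNA")
  truth$pA_handover <- FALSE
  idx <- which(is_next)
  if (length(idx))
    truth$pA_handover[idx] <- runif(length(idx)) < cfg$handover_fraction
  truth$effect_size <- ifelse(truth$pathway == "none", 0, cfg$effect_size)
  truth$rnai_extra <- ifelse(
    truth$feature == "SA_regular" & !is.na(truth$length_class),
    cfg$rnai_indirect_slope[truth$length_class], 0)
  # planted footprint: 3 nt ending at the focal (3'-most) position
  truth$start <- ifelse(truth$strand == "+", truth$focal - 2L, truth$focal)
  truth$end <- ifelse(truth$strand == "+", truth$focal + 1L,
                      truth$focal + 3L)
  truth$pa_share <- ifelse(truth$feature == "PAS", 0.9,
                    ifelse(truth$pathway == "PAXT", 0.8,
                    ifelse(truth$pathway == "both", 0.5,
                           cfg$pa_base_share)))
  truth[, c("cluster_id", "chrom", "start", "end", "strand", "focal",
            "feature", "pathway", "kinetic", "pA_handover", "intron_id",
            "intron_length", "length_class", "trimming_target", "sno_gap",
            "base_mean", "pa_share", "effect_size", "rnai_extra")]
}

#' Planted log2 fold change of truth clusters for a condition
#'
#' Encodes the planted effect rules: NEXT-pathway clusters respond to
#' ZCCHC8 and EXOSC3 depletion, PAXT-pathway clusters to ZFC3H1 and EXOSC3,
#' `both` clusters to all three, `none` to none.  Under AID, ZCCHC8
#' depletion responses plateau (full effect from 2 h on) while ZFC3H1 and
#' EXOSC3 responses grow linearly in time (`t/6` of the effect); RNAi
#' responses carry the full effect plus, for regular-intron SA clusters
#' under ZCCHC8 RNAi, the intron-length-scaled indirect extra effect.
#'
#' @param truth Truth table from [simulate_tracks()].
#' @param target Depletion target (`"ctrl"` gives all zeros).
#' @param method `"AID"` or `"RNAi"`.
#' @param timepoint_h IAA time in h for AID (0 gives all zeros).
#' @return Numeric vector of log2 fold changes, one per truth row.
#' @export
true_log2fc <- function(truth, target, method, timepoint_h = NA) {
  n <- nrow(truth)
  if (target == "ctrl" || (method == "AID" &&
                           (is.na(timepoint_h) || timepoint_h == 0)))
    return(rep(0, n))
  responds <- switch(target,
    ZCCHC8 = truth$pathway %in% c("NEXT", "both"),
    ZFC3H1 = truth$pathway %in% c("PAXT", "both"),
    EXOSC3 = truth$pathway %in% c("NEXT", "PAXT", "both"),
    rep(FALSE, n))
  if (method == "AID") {
    f <- if (target == "ZCCHC8") as.numeric(timepoint_h >= 2)
         else timepoint_h / 6
    lfc <- ifelse(responds, truth$effect_size * f, 0)
  } else {
    lfc <- ifelse(responds, truth$effect_size, 0)
    if (target == "ZCCHC8") lfc <- lfc + truth$rnai_extra
  }
  lfc
}

smear_active <- function(target, method, timepoint_h) {
  target == "EXOSC3" &&
    (method == "RNAi" || (!is.na(timepoint_h) && timepoint_h > 0))
}

#' Simulate per-library 3' end tracks and the ground-truth table
#'
#' Draws, for every library in the design, NB counts per planted cluster
#' (`variance = mu + alpha mu^2`) at the condition's planted fold change,
#' splits them into independently drawn pA+ and pA- components (a pA+
#' library observes the former, a pA+/- library their sum), distributes
#' each cluster's count over a 3 nt footprint peaking at the focal 3' end
#' position, and — in EXOSC3 depletion conditions — replaces `smear_frac`
#' of each trimming target's signal by a truncated-Gaussian smear of 3'
#' ends upstream of the SA.  Handover clusters shift signal into the pA+
#' fraction under ZCCHC8 depletion.  Per-cluster multiplicative batch
#' offsets (sdlog2 `batch_sd`) apply to non-reference batches.
#' Deterministic given `cfg$seed`.
#'
#' @param ann Annotation from [simulate_annotation()].
#' @param cfg A `sim_config`.
#' @param design Library sheet as from [default_design()]; must contain the
#'   reference libraries of every contrast.  An optional `depth` column
#'   scales library depth.
#' @return List with `tracks` (named list of raw `end_track`) and `truth`
#'   (data.frame; see [true_log2fc()]).
#' @export
simulate_tracks <- function(ann, cfg, design) {
  stopifnot(inherits(ann, "annotation"), inherits(cfg, "sim_config"))
  validate_design(design)
  withr::with_seed(cfg$seed + 1L, simulate_tracks_impl(ann, cfg, design))
}

simulate_tracks_impl <- function(ann, cfg, design) {
  truth <- build_truth(ann, cfg)
  n <- nrow(truth)
  if (is.null(design$depth)) design$depth <- 1
  if (is.null(design$batch)) design$batch <- NA_character_
  batches <- setdiff(unique(design$batch[!is.na(design$batch)]), character(0))
  ref_batch <- if (length(batches)) sort(batches)[1] else NA_character_
  batch_off <- matrix(0, n, length(batches),
                      dimnames = list(NULL, batches))
  for (b in setdiff(batches, ref_batch))
    batch_off[, b] <- rnorm(n, 0, cfg$batch_sd)

  size <- if (cfg$alpha > 0) 1 / cfg$alpha else Inf
  draw_nb <- function(mu) {
    if (is.infinite(size)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = size)
  }
  foot_off <- c(-2L, -1L, 0L)      # transcription-orientation offsets
  foot_p <- c(0.15, 0.25, 0.6)

  tracks <- vector("list", nrow(design))
  names(tracks) <- design$library_id
  sign <- ifelse(truth$strand == "+", 1L, -1L)
  sa_pos <- truth$focal + sign    # SA position (focal is offset -1)

  for (li in seq_len(nrow(design))) {
    d <- design[li, ]
    lfc <- true_log2fc(truth, d$target, d$method, d$timepoint_h)
    mu <- truth$base_mean * 2^lfc * d$depth
    if (!is.na(d$batch) && d$batch %in% colnames(batch_off))
      mu <- mu * 2^batch_off[, d$batch]
    share <- truth$pa_share
    ho <- truth$pA_handover & d$target == "ZCCHC8" & lfc > 0
    share[ho] <- cfg$handover_share
    if (d$pA_mode == "pA+") {
      counts <- draw_nb(share * mu)
    } else {
      counts <- draw_nb(share * mu) + draw_nb((1 - share) * mu)
    }
    smear_on <- smear_active(d$target, d$method, d$timepoint_h)
    pieces <- vector("list", n)
    for (ci in seq_len(n)) {
      k <- counts[ci]
      if (k == 0) next
      k_smear <- 0L
      if (smear_on && truth$trimming_target[ci] && cfg$smear_frac > 0)
        k_smear <- stats::rbinom(1, k, cfg$smear_frac)
      k_foot <- k - k_smear
      pos <- integer(0); cnt <- integer(0)
      if (k_foot > 0) {
        mm <- as.integer(stats::rmultinom(1, k_foot, foot_p))
        pos <- truth$focal[ci] + sign[ci] * foot_off
        cnt <- mm
      }
      if (k_smear > 0) {
        lim <- -1L
        lo_lim <- -min(150L, max(20L, truth$sno_gap[ci] - 5L, na.rm = TRUE))
        offs <- rtrunc_norm_int(k_smear, -cfg$smear_center, cfg$smear_sd,
                                lo_lim, lim)
        sm_pos <- sa_pos[ci] + sign[ci] * offs
        tb <- table(sm_pos)
        pos <- c(pos, as.integer(names(tb)))
        cnt <- c(cnt, as.integer(tb))
      }
      keep <- cnt > 0
      if (!any(keep)) next
      pieces[[ci]] <- data.frame(pos = pos[keep], value = cnt[keep],
                                 chrom = truth$chrom[ci],
                                 strand = truth$strand[ci])
    }
    df <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    tracks[[li]] <- end_track(df, d$library_id, normalized = FALSE)
  }
  list(tracks = tracks, truth = truth)
}

# integer draws from a truncated normal on [lo, hi] via inverse CDF
rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo - 0.5, mean, sd); phi <- pnorm(hi + 0.5, mean, sd)
  u <- runif(n, plo, phi)
  x <- round(qnorm(u, mean, sd))
  pmin(pmax(x, lo), hi)
}

#' Simulate a cluster count matrix directly
#'
#' Counts-level companion to [simulate_tracks()] for calibration studies:
#' baseline means are log-normal, counts NB with `variance = mu + alpha
#' mu^2`, and non-reference groups receive the given per-cluster log2 fold
#' changes.
#'
#' @param n_clusters Number of clusters.
#' @param n_per_group Named integer vector of libraries per group; the
#'   first group is the reference.
#' @param log2fc Scalar or per-cluster vector applied to non-reference
#'   groups; default 0.
#' @param mu_log Mean of `log(mu)`; default `log(150)`.
#' @param sdlog sdlog of baseline means; default 0.6.
#' @param alpha NB dispersion; default 0.05.
#' @param seed Seed.
#' @return List: `counts` (matrix with cluster/library dimnames),
#'   `condition` (factor per library), `mu` (baseline means), `log2fc`.
#' @export
simulate_cluster_counts <- function(n_clusters, n_per_group,
                                    log2fc = 0, mu_log = log(150),
                                    sdlog = 0.6, alpha = 0.05, seed = 1) {
  stopifnot(length(n_per_group) >= 2, !is.null(names(n_per_group)))
  log2fc <- rep_len(log2fc, n_clusters)
  withr::with_seed(seed, {
    mu <- stats::rlnorm(n_clusters, mu_log, sdlog)
    size <- if (alpha > 0) 1 / alpha else Inf
    cols <- list(); cond <- character(0)
    for (gi in seq_along(n_per_group)) {
      fc <- if (gi == 1) rep(1, n_clusters) else 2^log2fc
      for (r in seq_len(n_per_group[gi])) {
        m <- mu * fc
        cols[[length(cols) + 1L]] <-
          if (is.infinite(size)) rpois(n_clusters, m)
          else rnbinom(n_clusters, mu = m, size = size)
        cond <- c(cond, names(n_per_group)[gi])
      }
    }
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(sprintf("c_%05d", seq_len(n_clusters)),
                             sprintf("%s_r%d", cond,
                                     unlist(lapply(n_per_group, seq_len))))
    list(counts = counts, condition = factor(cond, names(n_per_group)),
         mu = mu, log2fc = log2fc)
  })
}
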