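#!/usr/bin/env Rscript
# Stage 6: metagene profiles at splice-acceptor anchors and the in-silico
# trimming index.
#
# Profiles are log2 ratios of anchor-summed normalized coverage (treated
# over matched reference, pseudocount 1) at single-nucleotide resolution,
# 150 nt upstream to 100 nt downstream of SA sites of snoRNA-hosting
# introns.  The trimming index contrasts SA-distal ([-150,-20]) against
# SA-proximal ([-10,0]) signal.

suppressPackageStartupMessages(library(exosens))

ann <- read_annotation("results/sim/annotation.gtf")
design <- read.table("results/sim/design.tsv", sep = "\t", header = TRUE)
sft <- read.table("results/normalization/size_factors.tsv", sep = "\t",
                  header = TRUE)
sf <- setNames(sft$size_factor, sft$library_id)

lib_of <- function(target, t) design$library_id[
  design$method == "AID" & design$target == target &
  design$timepoint_h == t & design$pA_mode == "pA+/-" &
  design$replicate == 1]
get_track <- function(lib) normalize_counts(
  read_endtrack_pair(file.path("results/sim/tracks", lib),
                     library_id = lib), sf)

anchors <- sa_anchors(ann, hosting = TRUE)
cat(sprintf("%d snoRNA-hosting SA anchors\n", nrow(anchors)))
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

trim <- numeric(0)
for (tg in c("ZCCHC8", "EXOSC3")) {
  tr <- get_track(lib_of(tg, 6))
  rf <- get_track(lib_of(tg, 0))
  prof <- metagene(tr, rf, anchors, upstream = 150, downstream = 100,
                   pseudocount = 1, chrom_lengths = ann$seqlengths)
  write.table(as.data.frame(prof),
              file.path("results/profiles",
                        paste0("metagene_", tg, "_6h_sno_sa.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  peak <- prof$offset[which.max(prof$value)]
  cat(sprintf("%s 6 h metagene maximum at offset %+d (value %.2f)\n",
              tg, peak, max(prof$value)))
  trim[paste0(tg, "_6h")] <- insilico_trimming_index(tr, anchors)
}
write.table(data.frame(condition = names(trim),
                       trimming_index = unname(trim)),
            "results/profiles/trimming_index.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("in-silico trimming index: EXOSC3 6 h %.2f vs ZCCHC8 6 h %.4f\n",
            trim[["EXOSC3_6h"]], trim[["ZCCHC8_6h"]]))
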