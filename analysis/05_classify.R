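#!/usr/bin/env Rscript
# Stage 5: sensitivity scores, NEXT/PAXT target classification,
# composition and intron-length stratification.
#
# Sensitivity = (treated - ctrl)/max(ctrl, treated, 1) on replicate-mean
# normalized counts.  The stringent targeting classes intersect the RNAi
# and 6 h AID upregulated sets per pathway (pA modes unioned per method)
# and then remove clusters claimed by both pathways.

suppressPackageStartupMessages(library(exosens))

design <- read.table("results/sim/design.tsv", sep = "\t", header = TRUE)
sft <- read.table("results/normalization/size_factors.tsv", sep = "\t",
                  header = TRUE)
sf <- setNames(sft$size_factor, sft$library_id)
cm <- read.table("results/clusters/cluster_counts.tsv", sep = "\t",
                 header = TRUE, check.names = FALSE)
counts <- as.matrix(cm[, -1]); rownames(counts) <- cm$cluster_id
clusters <- read.table("results/clusters/clusters.tsv", sep = "\t",
                       header = TRUE)
cl_ann <- read.table("results/clusters/cluster_annotation.tsv", sep = "\t",
                     header = TRUE)
ann <- read_annotation("results/sim/annotation.gtf")

contrasts <- build_contrasts(design)
norm_counts <- normalize_counts(counts, sf)
sens <- sensitivity_matrix(norm_counts, contrasts)
dir.create("results/targeting", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(cluster_id = rownames(sens), sens,
                       check.names = FALSE),
            "results/targeting/sensitivity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

up <- lapply(names(contrasts), function(nm) {
  de <- read.table(file.path("results/differential",
                             paste0("de_", nm, ".tsv")),
                   sep = "\t", header = TRUE)
  call_upregulated(de)
})
names(up) <- names(contrasts)
u <- function(prefix)
  union_pa_modes(unlist(up[startsWith(names(up), prefix)]))

classes <- classify_targets(u("RNAi_ZCCHC8"), u("AID_ZCCHC8_6h"),
                            u("RNAi_ZFC3H1"), u("AID_ZFC3H1_6h"))
cat(sprintf("RNAi+AID classes: %d NEXT, %d PAXT (candidates %d/%d before exclusion)\n",
            length(classes$NEXT), length(classes$PAXT),
            length(classes$NEXT_candidates),
            length(classes$PAXT_candidates)))
write.table(data.frame(
  cluster_id = c(classes$NEXT, classes$PAXT),
  class = rep(c("NEXT", "PAXT"),
              c(length(classes$NEXT), length(classes$PAXT)))),
  "results/targeting/target_classes.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

cat("\nbiotype composition of the NEXT class (%):\n")
print(round(composition(classes$NEXT, cl_ann, "biotype"), 1))
cat("\nbiotype composition of the PAXT class (%):\n")
print(round(composition(classes$PAXT, cl_ann, "biotype"), 1))

# regular-intron SA stratification by length class
anchors <- sa_anchors(ann, hosting = FALSE)
cond <- names(up)[startsWith(names(up), "RNAi_ZCCHC8") |
                  startsWith(names(up), "AID_ZCCHC8")]
tab <- sa_overlap_fraction(anchors, up[cond], clusters, sa_window = 10)
write.table(tab, "results/targeting/sa_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nSA sites overlapping upregulated clusters (% per intron length class):\n")
print(tab[tab$condition %in% c("RNAi_ZCCHC8_pAall", "AID_ZCCHC8_2h_pAall",
                               "AID_ZCCHC8_6h_pAall"), ])
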