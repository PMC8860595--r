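#!/usr/bin/env Rscript
# Stage 3: 3' end cluster calling, quantification and annotation.
#
# Pools raw signal across all libraries, seeds clusters at positions with
# pooled count >= 3, merges seeds within 25 nt per strand, then counts raw
# 3' ends per cluster per library and assigns each cluster one biotype and
# (within protein-coding genes) one feature label.

suppressPackageStartupMessages(library(exosens))

ann <- read_annotation("results/sim/annotation.gtf")
design <- read.table("results/sim/design.tsv", sep = "\t", header = TRUE)
tracks <- lapply(design$library_id, function(lib)
  read_endtrack_pair(file.path("results/sim/tracks", lib), library_id = lib))
names(tracks) <- design$library_id

clusters <- call_clusters(tracks, min_pos_count = 3, max_gap = 25)
counts <- count_matrix(clusters, tracks)
cl_ann <- annotate_clusters(clusters, ann, sa_window = 10)

dir.create("results/clusters", showWarnings = FALSE, recursive = TRUE)
write.table(clusters, "results/clusters/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(cluster_id = rownames(counts), counts,
                       check.names = FALSE),
            "results/clusters/cluster_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cl_ann, "results/clusters/cluster_annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.table("results/sim/truth.tsv", sep = "\t", header = TRUE)
mt <- match_truth_clusters(truth, clusters)
cat(sprintf("called %d clusters; %.1f%% of planted clusters recovered at Jaccard >= 0.8\n",
            nrow(clusters), 100 * mean(mt$jaccard >= 0.8)))
cat("biotype composition of called clusters:\n")
print(table(cl_ann$biotype))
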