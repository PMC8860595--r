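#!/usr/bin/env Rscript
# Stage 2: library-size normalization anchored on last exons.
#
# Bulk mRNA 3' ends in last exons of protein-coding genes are assumed
# insensitive to exosome/adaptor depletion; their summed counts (filtered
# for >100 reads in at least one library, pseudocount 1) feed a
# median-of-ratios size-factor estimate per library.

suppressPackageStartupMessages(library(exosens))

ann <- read_annotation("results/sim/annotation.gtf")
design <- read.table("results/sim/design.tsv", sep = "\t", header = TRUE)
tracks <- lapply(design$library_id, function(lib)
  read_endtrack_pair(file.path("results/sim/tracks", lib), library_id = lib))
names(tracks) <- design$library_id

lem <- last_exon_matrix(tracks, ann)
kept <- filter_expressed(lem, min_reads = 100)
cat(sprintf("last exons: %d quantified, %d pass the expression filter\n",
            nrow(lem), nrow(kept)))

sf <- size_factors(kept, pseudocount = 1)
dir.create("results/normalization", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(library_id = names(sf), size_factor = unname(sf)),
            "results/normalization/size_factors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("size factors span %.3f - %.3f (libraries at equal planted depth)\n",
            min(sf), max(sf)))
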