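#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the full depletion design: ZCCHC8 (NEXT), ZFC3H1 (PAXT) and
# EXOSC3 (core exosome) depleted either rapidly (auxin degron, 0/2/6 h,
# duplicates) or long-term (RNAi vs control knockdown, triplicates in two
# library-prep batches), each sequenced as pA+ and pA+/- 3' end libraries.
# Writes the annotation (GTF), per-library strand-specific bedGraph tracks,
# the library sheet and the planted ground truth under results/sim/.

suppressPackageStartupMessages(library(exosens))

outdir <- "results/sim"
dir.create(file.path(outdir, "tracks"), recursive = TRUE,
           showWarnings = FALSE)

cfg <- sim_config(seed = 42)
design <- default_design()

ann <- simulate_annotation(cfg)
print(ann)

sim <- simulate_tracks(ann, cfg, design)

write_annotation(ann, file.path(outdir, "annotation.gtf"))
write.table(design, file.path(outdir, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (lib in names(sim$tracks))
  write_endtrack(sim$tracks[[lib]], file.path(outdir, "tracks", lib))

tot <- vapply(sim$tracks, track_total, numeric(1))
cat(sprintf("wrote %d libraries (median depth %s 3' ends) and %d planted clusters\n",
            length(sim$tracks), format(median(tot)), nrow(sim$truth)))
cat("planted pathway composition:\n")
print(table(sim$truth$pathway))
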