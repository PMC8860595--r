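# exosens

Quantification and classification of nuclear exosome RNA targets from
strand-specific transcript 3′ end sequencing.

## The problem this package addresses

The nuclear RNA exosome degrades a large share of the RNA polymerase II
output, delivered by two nucleoplasmic adaptors: the **NEXT** complex
(MTR4–ZCCHC8–RBM7; nonadenylated substrates such as PROMPTs, eRNAs and
snoRNA-hosting intron intermediates) and the **PAXT** connection
(MTR4–ZFC3H1; polyadenylated nuclear RNAs). Depleting these factors by
RNAi takes days and accumulates indirect effects; auxin-degron (AID)
depletion removes them in hours. Comparing 3′ end sequencing responses
between the two regimes distinguishes direct substrates (upregulated in
both) from indirect ones (upregulated only after long-term depletion).

`exosens` is aimed at computational biologists analyzing such data. It
implements, as a tested R package plus a scripted workflow:

- **Normalization** anchored on last exons of protein-coding genes
  (assumed depletion-insensitive): filter exons at >100 reads in at least
  one library, add a pseudocount of 1, estimate median-of-ratios size
  factors.
- **3′ end cluster calling** on pooled signal (seed threshold 3, merge
  gap 25 nt), per-library counting, and biotype/feature annotation with
  deterministic priorities.
- **Differential expression** per cluster: NB GLM
  (`variance = μ + αμ²`, method-of-moments dispersion shrunk to a
  mean-dispersion trend) with Wald tests against the matched reference
  (AID: same line at 0 h; RNAi: control knockdown, with a batch
  covariate), BH adjustment, and strict upregulation calls
  (log₂FC > 1, P_adj < 0.1).
- **The sensitivity statistic**
  `sensitivity = (treated − ctrl) / max(ctrl, treated, 1)`,
  bounded in [−1, 1]: 1 when signal is exclusive to the depletion, −1
  when exclusive to the control, 0 when equal.
- **Targeting classes**: intersect RNAi and 6 h AID upregulated sets per
  pathway (pA⁺ and pA⁺/⁻ calls unioned per method), then enforce mutual
  exclusion between NEXT and PAXT.
- **Metagene profiles** at single-nucleotide resolution around oriented
  splice-acceptor (SA) anchors (150 nt upstream, 100 nt downstream,
  log₂ ratio with pseudocount 1) and an **exonucleolytic trimming
  readout** — the distal/proximal amplicon ratio and an in-silico index
  contrasting SA-distal `[−150, −20]` with SA-proximal `[−10, 0]`
  3′ end signal.
- A **synthetic-data generator** that plants all of the structure above
  (NB counts, plateau vs progressive kinetics, pA⁻→pA⁺ handover,
  RNAi-only intron-length-scaled SA effects, EXOSC3 trimming smears) with
  a ground-truth table, so the whole pipeline is testable offline.

Input formats are the field's standards: GTF/BED12 annotations, one
bedGraph per strand per library (`.plus.bedgraph` / `.minus.bedgraph`),
TSV metadata and result tables.

## Worked example

```r
library(exosens)

# the sensitivity statistic at its defining points
sensitivity(c(37, 58, 0, 3), c(0, 58, 12, 1))
#> [1]  1.0000000  0.0000000 -1.0000000  0.6666667

# a full synthetic run: simulate -> normalize -> cluster -> DE ->
# classify -> stratify -> profile
res <- run_pipeline(pipeline_config(
  sim = sim_config(seed = 5, n_genes = 30, n_lncrna = 6, n_ernas = 12)))

lengths(res$classes[c("NEXT", "PAXT")])
#> NEXT PAXT
#>   53   24

round(composition(res$classes$NEXT, res$cluster_annotation, "biotype"), 1)
#>           eRNA         lncRNA         PROMPT protein_coding
#>            5.7            1.9           20.8           71.7

subset(res$sa_overlap, condition == "RNAi_ZCCHC8_pAall")
#>            condition length_class n_sa n_up fraction
#> 16 RNAi_ZCCHC8_pAall        short   50    0  0.00000
#> 17 RNAi_ZCCHC8_pAall       medium   38    6 15.78947
#> 18 RNAi_ZCCHC8_pAall         long   33   30 90.90909

round(res$trimming, 3)
#> ZCCHC8_6h EXOSC3_6h
#>      0.00      2.92
```

Reading the output: 53 clusters classify as exclusive NEXT targets and 24
as PAXT targets, with the NEXT class enriched for PROMPTs and eRNAs plus
protein-coding–internal 3′ ends (mostly snoRNA-hosting SA sites). The SA
stratification shows the planted long-term-only intron phenotype — under
ZCCHC8 RNAi the fraction of regular-intron SA sites overlapping
upregulated clusters climbs from 0% (short) through 16% (medium) to 91%
(long introns), while the 2 h AID condition stays flat. The trimming
index separates the smeared EXOSC3 depletion signal (2.92, 3′ ends
scattered upstream of the SA) from the sharp SA peak under ZCCHC8
depletion (≈ 0).

The same stages can be run as a file-passing workflow:

```sh
Rscript analysis/01_simulate.R      # annotation, tracks, truth -> results/sim/
Rscript analysis/02_normalize.R     # size factors
Rscript analysis/03_cluster_quant.R # clusters, counts, annotation
Rscript analysis/04_differential.R  # per-contrast DE + PCA
Rscript analysis/05_classify.R      # sensitivity, classes, SA stratification
Rscript analysis/06_profiles.R      # metagenes + trimming index
```

## Package layout

- `R/` — implementation: interval/annotation/track core, synthetic
  generator, normalization, cluster calling, NB differential expression,
  sensitivity/classification, metagene/trimming, pipeline orchestration.
- `analysis/` — numbered workflow drivers over the package.
- `tests/testthat/` — unit, property and acceptance-level tests with
  independent brute-force oracles.
- `vignettes/exosens-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, what the synthetic data do and do not
  emulate, known limitations.
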