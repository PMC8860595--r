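---
title: "Quantifying nuclear exosome RNA targeting from 3' end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear exosome RNA targeting from 3' end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exosens)
```

## The scientific problem

Nucleoplasmic RNA turnover in human cells is dominated by the RNA exosome,
a 3'–5' exo/endonucleolytic complex delivered to its substrates by two
adaptors: the NEXT complex (MTR4–ZCCHC8–RBM7, targeting nonadenylated
RNAs such as PROMPTs, eRNAs and snoRNA-hosting intron intermediates) and
the PAXT connection (MTR4–ZFC3H1, targeting polyadenylated nuclear RNAs).
Loss-of-function studies of these factors traditionally rely on RNAi,
which takes days and lets indirect effects accumulate; auxin-degron (AID)
tagging removes the same proteins within hours.  Comparing transcriptomic
responses between the two depletion regimes separates direct substrates
(responding in both) from indirect ones (responding only after long-term
depletion).

`exosens` implements the quantitative core of such a comparison for
strand-specific transcript 3' end sequencing: last-exon anchored
normalization, 3' end cluster calling and annotation, negative-binomial
differential expression against matched references, a bounded
depletion-sensitivity statistic, intersection-based classification into
mutually exclusive NEXT/PAXT targeting classes, single-nucleotide metagene
profiles around splice-acceptor (SA) anchors, and an exonucleolytic
trimming readout.  A synthetic-data generator plants the statistical
structure this analysis assumes, so every stage is testable without any
external download.

## Coordinates and domain objects

All genomic coordinates are 0-based, half-open `[start, end)`, with
mandatory strand; GTF input (1-based closed) is converted on read.  A
transcript 3' end is recorded at its last transcribed nucleotide.  The SA
position of an intron is the first nucleotide of the downstream exon in
transcription orientation, so excised-intron 3' ends accumulate at
transcription-orientation offset −1.  These conventions remove all
off-by-one ambiguity from metagene offsets: the anchor sits at offset 0,
upstream offsets are negative.

Tracks (`end_track`) are sparse per-position maps of 3' end counts;
positions absent from the map read as zero, and raw versus normalized
state is an explicit flag.  Annotations carry genes with biotypes
(`protein_coding`, `lncRNA`, `PROMPT`, `eRNA`, `snoRNA`), derived introns
with SA positions and snoRNA-hosting flags, and last exons.

## Normalization

Normalization assumes bulk mRNA is insensitive to exosome depletion:
3' end counts are summed in last exons of protein-coding genes, rows are
kept when some library exceeds 100 reads (strictly), a pseudocount of 1 is
added, and median-of-ratios size factors are computed against the per-row
geometric mean.  Two numerical choices are fixed for reproducibility: the
pseudocount enters before the ratio (so all-zero rows are usable), and
even-length medians take the lower central value.  Size factors are
defined up to the geometric-mean reference; only their ratios are
meaningful, which is what both the tests and the depletion analyses use.
One algorithm serves both the AID and RNAi arms; the package does not
attempt to reproduce two historically different implementations of the
same idea.

## Cluster calling, counting, annotation

Proximal 3' end positions are aggregated on the pooled raw signal of all
libraries: positions with pooled count ≥ 3 seed clusters, seeds within
25 nt on a strand merge (single linkage), and the cluster spans
`[min seed, max seed + 1)` with the summit at the pooled maximum (5'-most
on ties).  These caller parameters are package defaults, exposed in the
configuration — cluster coordinates in the original studies came from
pre-existing catalogs, so a self-contained pipeline needs its own caller.

Each cluster receives one biotype by strand-specific overlap with priority
`PROMPT > eRNA > snoRNA > lncRNA > protein_coding > not_annotated`, and,
within protein-coding genes, one feature from the summit with priority
`SA_snoRNA_host > SA_regular > PAS > ptRNA > exonic > intronic`.  The
priorities order labels from most to least specific so that percentages in
composition summaries are well defined (one label per cluster).  A summit
within 10 nt upstream of an SA (offset in `[-10, 0]`) is "at" that SA;
TSS-proximal sense summits (≤ 3 kb downstream of the TSS) are labelled
`ptRNA`, the biological reading of promoter-proximal premature
termination.  Overlaps are strand-specific throughout — 3' end data are
strand-resolved, and mixing strands would conflate sense and antisense
transcription units.

## Differential expression

Counts are modelled as negative binomial with `variance = mu + alpha mu^2`.
Per-cluster dispersion is a pooled within-group method-of-moments
estimate shrunk toward a fitted `alpha(mu) = a0 + a1/mu` trend with fixed
weight 0.85, floored at `1e-6`.  The heavy trend weight is deliberate:
with duplicate libraries the per-cluster moment estimate has essentially
two degrees of freedom, and the trend (fit across thousands of clusters)
carries most of the usable information.  Each cluster is then fit with a
log-link NB GLM at fixed dispersion (`count ~ condition (+ batch)`, size
factors as offsets) and tested by Wald.  One subtlety matters: the
summary dispersion is pinned to 1 so that standard errors come from the
NB information alone — a residual-based quasi-dispersion would be
degenerate at two replicates per group.  Non-converged or unstable fits
(|log fold change| > 30 natural-log units) are reported as `NA` and
excluded from BH adjustment rather than crashing the run.  Upregulation
calls are strict on both axes: `log2FC > 1` and `padj < 0.1`.

This estimator is validated by calibration and recovery rather than by
matching any external package bit-for-bit: on a global-null simulation
(2000 clusters, 2 vs 2) the raw p < 0.05 fraction sits in 0.05 ± 0.02 and
essentially nothing passes the joint thresholds; with 10% of clusters
planted at log2FC = 2 it recovers ≥ 80% of them at an empirical FDR
below 15%.

PCA uses `log2(normalized count + 1)` as a fully specified stand-in for a
variance-stabilizing transformation, ranks clusters by variance across
libraries, keeps the top 2000 and decomposes the centered matrix by SVD.

## Sensitivity and target classification

The depletion response of a cluster is summarized by

```
sensitivity = (treated − ctrl) / max(ctrl, treated, 1)
```

on replicate-averaged normalized counts (arithmetic means, matching
per-sample heatmap columns).  The statistic is bounded in `[-1, 1]`:
signal exclusive to the depletion gives 1, exclusive to the control −1,
equal signal 0, and the unit floor keeps sub-unit signals away from the
bounds.  AID contrasts use the same line's 0 h libraries as reference,
RNAi contrasts the control knockdown.

Stringent targeting classes intersect the RNAi and 6 h AID upregulated
sets per pathway (ZCCHC8 depletions for NEXT, ZFC3H1 for PAXT), after
unioning pA+ and pA+/− calls within each method, then remove clusters
claimed by both pathways, yielding mutually exclusive classes.  Unioning
across pA modes (rather than intersecting) is the default because a
substrate may legitimately surface in only one 3' end chemistry — e.g. a
nonadenylated intermediate in pA+/− only; the choice is exposed to
callers, who can intersect instead by passing pre-intersected sets.
Mutual exclusion is applied after the method intersection, mirroring the
construction of the classes this analysis emulates.

## Metagenes and the trimming readout

Metagene profiles extract, per anchor, the oriented window 150 nt
upstream to 100 nt downstream (minus-strand windows reversed so offsets
follow transcription), sum coverage across anchors per offset for treated
and reference separately, and report `log2((T + 1)/(R + 1))`.  Summing
before the single log ratio is the default because per-anchor log ratios
explode on the many anchors with zero coverage; the per-anchor mean is
available behind a flag.  Anchors whose window leaves the chromosome are
dropped, not clipped, keeping the per-offset denominator uniform.

The qPCR-style trimming factor is the ratio of SA-distal to SA-proximal
reference-normalized amplicon quantities; a common stabilization of both
amplicons cancels exactly, so values above 1 isolate partially 3'-trimmed
species.  The in-silico counterpart ratios pseudocounted track signal in
an SA-distal window `[-150, -20]` against an SA-proximal window
`[-10, 0]` (inclusive transcription-orientation offsets).  The window
bounds are package choices, set to bracket the ~50 nt upstream positional
bias of trimming intermediates while excluding the SA peak itself.

## What the synthetic data emulate

The generator is the package's statement of the study conditions:

* **Design**: ZCCHC8, ZFC3H1 and EXOSC3 depletions; AID time courses
  (0/2/6 h, duplicates) and RNAi versus control knockdown (triplicates,
  two library-prep batches), each as pA+ and pA+/− libraries.
* **Annotation**: multi-intron protein-coding genes with antisense PROMPT
  regions, intron-hosted snoRNAs (3' ends 180–260 nt upstream of the host
  SA), lncRNA genes and intergenic eRNA loci.  Intron lengths mix the
  three analysis classes (< 700, 700–4000, > 4000 nt) equally.
* **Counts**: log-normal baseline means (sdlog 0.6 — wide enough to span
  an order of magnitude, narrow enough that planted effects stay within
  reach of the shallow simulated depth), NB dispersion `alpha = 0.05`.
* **Effects**: pathway effect 2 in log2 units.  NEXT targets respond to
  ZCCHC8 and EXOSC3, PAXT targets to ZFC3H1 and EXOSC3, dual targets to
  all three.  Under AID, ZCCHC8 responses plateau (full effect from 2 h)
  while ZFC3H1/EXOSC3 responses grow linearly in time — the kinetic
  encoding is an explicit simplification; the emulated experiments show
  these shapes but do not parameterize rates.
* **Handover**: a fraction of NEXT targets shifts signal into the pA+
  fraction under ZCCHC8 depletion while the pA+/− signal persists,
  emulating post-transcriptional adenylation and failsafe handover to
  PAXT.
* **Indirect RNAi effects**: regular-intron SA clusters gain an extra
  RNAi-only log2FC of 0/0.7/1.5 for short/medium/long introns under
  ZCCHC8 knockdown, planting the length-scaled, long-term-only intron
  phenotype.
* **Trimming**: in EXOSC3 depletion conditions, 80% of each
  snoRNA-hosting SA cluster's signal is redistributed into a truncated
  Gaussian of 3' ends centered 50 nt upstream of the SA (sd 30 nt),
  bounded away from the hosted snoRNA.

Everything is deterministic given the seed (randomness funnels through
one seeded generator per stage).  What the simulation does *not* contain:
mechanistic decay kinetics, read-level error, mappability artifacts,
overlapping transcription units, isoform complexity, or genuine biological
replicate variation beyond NB noise.  Passing tests therefore demonstrate
that the statistical machinery recovers planted structure under the
stated model — not that the model captures every property of real 3' end
libraries.

## Problem sizes and numerical choices

The bundled analyses and tests run at desk scale by design: tens of genes,
hundreds of clusters, tens of libraries — sizes at which every planted
effect is still comfortably detectable and a full pipeline run takes
seconds.  Degenerate inputs are handled explicitly: empty bedGraphs read
as all-zero tracks; clusters below the seed threshold simply do not
exist; an empty targeting class warns and returns an empty composition;
empty SA strata report `NA`; zero-variance matrices refuse PCA.  Ties are
fixed deterministically (lower median in size factors, 5'-most summit,
biotype/feature priority order), so identical configurations reproduce
byte-identical outputs.

## Known limitations

* The NB Wald test at two replicates per group leans on the dispersion
  trend; clusters whose true dispersion deviates far from the trend are
  tested at a misspecified alpha.  The calibration tests bound the
  aggregate consequence, not the per-cluster one.
* The cluster caller is intentionally simple (threshold + single
  linkage); it does not split adjacent 3' end sites closer than the merge
  gap.
* Sensitivity values compress all replicate information into two means;
  no uncertainty accompanies them, which is why classification rests on
  the Wald calls rather than on sensitivity thresholds.
* Feature annotation assigns one label per cluster; clusters genuinely
  spanning two features (e.g. a PAS immediately downstream of an SA) take
  the higher-priority label.
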