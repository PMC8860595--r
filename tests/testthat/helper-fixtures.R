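# Fixture builders and independent brute-force oracles shared across tests.
# All fixtures are generated in code; the heavier synthetic runs are built
# once per session and memoized.

# -- GTF fixture helpers ---------------------------------------------------

# one gene's GTF lines from 0-based half-open exons (list of c(start, end))
gtf_gene <- function(gene_id, chrom, strand, exons,
                     biotype = "protein_coding") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";',
                   gene_id, gene_id, biotype)
  vapply(exons, function(e) {
    sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
            chrom, e[1] + 1L, e[2], strand, attrs)
  }, character(1))
}

write_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

read_gtf_fixture <- function(...) read_annotation(write_gtf(c(...)))

# -- brute-force oracles ---------------------------------------------------

# per-nucleotide set overlap of two interval tables (strand-specific)
bf_overlap <- function(query, subjects) {
  hits <- list()
  for (qi in seq_len(nrow(query))) for (si in seq_len(nrow(subjects))) {
    if (query$chrom[qi] != subjects$chrom[si]) next
    if (query$strand[qi] != subjects$strand[si]) next
    qset <- seq.int(query$start[qi], query$end[qi] - 1L)
    sset <- seq.int(subjects$start[si], subjects$end[si] - 1L)
    if (length(intersect(qset, sset)) > 0)
      hits[[length(hits) + 1L]] <- data.frame(query = qi, subject = si)
  }
  if (length(hits) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  do.call(rbind, hits)
}

# single-linkage clustering of seed positions (one chrom/strand)
bf_single_linkage <- function(pos, max_gap) {
  pos <- sort(pos)
  if (length(pos) == 0) return(list())
  groups <- list(pos[1])
  for (p in pos[-1]) {
    last <- groups[[length(groups)]]
    if (p - max(last) <= max_gap)
      groups[[length(groups)]] <- c(last, p)
    else groups[[length(groups) + 1L]] <- p
  }
  groups
}

# sorted-formula BH: padj_i = min over j with p_(j) >= p_(i) of m p_(j) / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# per-nucleotide count of a track within an interval
bf_interval_sum <- function(track, chrom, start, end, strand) {
  df <- as.data.frame(track$counts)   # plain frame: no column-name capture
  s <- 0
  for (p in seq.int(start, end - 1L)) {
    v <- df$value[df$chrom == chrom & df$strand == strand & df$pos == p]
    if (length(v)) s <- s + sum(v)
  }
  s
}

# random sparse track on a small chromosome
random_track <- function(seed, n = 30, chrom_len = 1000, lib = "rnd") {
  withr::with_seed(seed, {
    pos <- sample.int(chrom_len, n) - 1L
    end_track(data.frame(chrom = "chrT", strand = sample(c("+", "-"), n,
                                                         replace = TRUE),
                         pos = pos, value = sample.int(20, n, replace = TRUE)),
              library_id = lib)
  })
}

# -- memoized synthetic runs ----------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# moderate synthetic dataset without the pipeline wrapper (no EXOSC3 arm:
# keeps planted footprints unsmeared for geometry checks)
sim_fixture <- function() {
  memo("sim_fixture", {
    cfg <- sim_config(seed = 101, n_genes = 20, n_lncrna = 4, n_ernas = 8)
    ann <- simulate_annotation(cfg)
    design <- default_design(targets = c("ZCCHC8", "ZFC3H1"),
                             aid_timepoints = c(0, 6), rnai_replicates = 2)
    sim <- simulate_tracks(ann, cfg, design)
    clusters <- call_clusters(sim$tracks)
    counts <- count_matrix(clusters, sim$tracks)
    lem <- last_exon_matrix(sim$tracks, ann)
    sf <- size_factors(filter_expressed(lem, 100), 1)
    list(cfg = cfg, ann = ann, design = design, tracks = sim$tracks,
         truth = sim$truth, clusters = clusters, counts = counts, sf = sf)
  })
}

# full pipeline run used by the acceptance-level checks
pipeline_fixture <- function() {
  memo("pipeline_fixture", {
    run_pipeline(pipeline_config(
      sim = sim_config(seed = 5, n_genes = 30, n_lncrna = 6, n_ernas = 12),
      outdir = NULL))
  })
}
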