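test_that("generator output is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_genes = 6, n_lncrna = 2, n_ernas = 3)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  design <- default_design(targets = "ZCCHC8", aid_timepoints = c(0, 6),
                           rnai = FALSE)
  s1 <- simulate_tracks(a1, cfg, design)
  s2 <- simulate_tracks(a2, cfg, design)
  expect_identical(s1$truth, s2$truth)
  for (lib in names(s1$tracks))
    expect_identical(as.data.frame(s1$tracks[[lib]]$counts),
                     as.data.frame(s2$tracks[[lib]]$counts))
})

test_that("intron length mixture is respected at the boundaries", {
  cfg <- sim_config(seed = 4, n_genes = 10, n_lncrna = 0, n_ernas = 0,
                    intron_mix = c(short = 1, medium = 0, long = 0))
  ann <- simulate_annotation(cfg)
  pc <- ann$genes$gene_id[ann$genes$biotype == "protein_coding"]
  lens <- ann$introns$length[ann$introns$gene_id %in% pc]
  expect_true(all(lens < 700))
  cfg2 <- sim_config(seed = 4, n_genes = 6, n_lncrna = 0, n_ernas = 0,
                     intron_mix = c(short = 0, medium = 0, long = 1))
  ann2 <- simulate_annotation(cfg2)
  lens2 <- ann2$introns$length[ann2$introns$gene_id %in%
                               ann2$genes$gene_id[ann2$genes$biotype ==
                                                  "protein_coding"]]
  expect_true(all(lens2 > 4000))
})

test_that("simulated counts match NB mean/variance at Monte-Carlo scale", {
  n <- 10000
  sim <- simulate_cluster_counts(n, c(ref = 1, treated = 1), log2fc = 2,
                                 mu_log = log(200), sdlog = 0, alpha = 0.05,
                                 seed = 21)
  k <- sim$counts[, 1]
  expect_equal(mean(k), 200, tolerance = 0.02)
  expect_equal(var(k), 200 + 0.05 * 200^2, tolerance = 0.1)
  # NB mean parameterization: planted log2FC = 2 gives mean ratio 4
  ratio <- mean(sim$counts[, 2]) / mean(sim$counts[, 1])
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("planted truth respects kinetic and pathway rules", {
  fx <- sim_fixture()
  truth <- fx$truth
  # plateau: ZCCHC8 AID effect equal at 2 h and 6 h; progressive grows
  l2 <- true_log2fc(truth, "ZCCHC8", "AID", 2)
  l6 <- true_log2fc(truth, "ZCCHC8", "AID", 6)
  nxt <- truth$pathway %in% c("NEXT", "both")
  expect_equal(l2[nxt], l6[nxt])
  p2 <- true_log2fc(truth, "ZFC3H1", "AID", 2)
  p6 <- true_log2fc(truth, "ZFC3H1", "AID", 6)
  pax <- truth$pathway %in% c("PAXT", "both")
  expect_true(all(p6[pax] > p2[pax]))
  expect_true(all(p2[pax] > 0))
  # non-targets never move under AID NEXT depletion; ctrl and 0 h are zero
  expect_true(all(l6[truth$pathway %in% c("none", "PAXT")] == 0))
  expect_equal(true_log2fc(truth, "ctrl", "RNAi"), rep(0, nrow(truth)))
  expect_equal(true_log2fc(truth, "ZCCHC8", "AID", 0), rep(0, nrow(truth)))
  # RNAi-only indirect effect at regular SAs scales with length class
  r <- true_log2fc(truth, "ZCCHC8", "RNAi")
  reg <- truth$feature == "SA_regular"
  expect_true(all(r[reg & truth$length_class == "short"] == 0))
  expect_true(all(r[reg & truth$length_class == "medium"] == 0.7))
  expect_true(all(r[reg & truth$length_class == "long"] == 1.5))
  expect_true(all(true_log2fc(truth, "ZCCHC8", "AID", 6)[reg] == 0))
})

test_that("EXOSC3 depletion smears trimming-target 3' ends upstream of the SA", {
  cfg <- sim_config(seed = 31, n_genes = 12, n_lncrna = 0, n_ernas = 0,
                    intron_mix = c(short = 0, medium = 0.5, long = 0.5),
                    frac_sno_host = 0.6)
  ann <- simulate_annotation(cfg)
  design <- default_design(targets = c("ZCCHC8", "EXOSC3"),
                           aid_timepoints = c(0, 6), aid_replicates = 1,
                           pa_modes = "pA+/-", rnai = FALSE)
  sim <- simulate_tracks(ann, cfg, design)
  truth <- sim$truth
  tt <- truth[truth$trimming_target, ]
  expect_gt(nrow(tt), 2)
  frac_distal <- function(track, row) {
    sa <- row$focal + ifelse(row$strand == "+", 1L, -1L)
    win <- function(lo, hi) {  # transcription-orientation offsets
      gpos <- sa + ifelse(row$strand == "+", 1L, -1L) * seq.int(lo, hi)
      dt <- track$counts
      sum(dt[dt$chrom == row$chrom & dt$strand == row$strand &
               dt$pos %in% gpos]$value)
    }
    all_sig <- win(-150, 5)
    if (all_sig == 0) return(NA_real_)
    win(-150, -20) / all_sig
  }
  ex6 <- sim$tracks[["AID_EXOSC3_6h_pAall_r1"]]
  z6 <- sim$tracks[["AID_ZCCHC8_6h_pAall_r1"]]
  fr_ex <- vapply(seq_len(nrow(tt)), function(i) frac_distal(ex6, tt[i, ]),
                  numeric(1))
  fr_z <- vapply(seq_len(nrow(tt)), function(i) frac_distal(z6, tt[i, ]),
                 numeric(1))
  expect_gt(median(fr_ex, na.rm = TRUE), 0.5)
  expect_lt(median(fr_z, na.rm = TRUE), 0.1)
})

test_that("pA handover moves NEXT-cluster signal into the pA+ library", {
  fx <- sim_fixture()
  truth <- fx$truth
  ho <- truth[truth$pA_handover, ]
  expect_gte(nrow(ho), 3)
  sum_at <- function(lib, rows) {
    iv <- rows[, c("chrom", "start", "end", "strand")]
    sum(exosens:::sum_in_intervals(fx$tracks[[lib]], iv))
  }
  plus0 <- sum_at("AID_ZCCHC8_0h_pAplus_r1", ho)
  plus6 <- sum_at("AID_ZCCHC8_6h_pAplus_r1", ho)
  all6 <- sum_at("AID_ZCCHC8_6h_pAall_r1", ho)
  # adenylated fraction gains strongly under depletion while the pA+/-
  # library retains at least as much signal as the pA+ one
  expect_gt(plus6, 4 * plus0)
  expect_gte(all6, plus6)
})
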