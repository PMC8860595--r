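test_that("intron derivation and SA positions follow the strand", {
  # plus strand: exons [100,200) and [500,700) -> intron [200,500), SA = 500
  ann <- read_gtf_fixture(
    gtf_gene("gp", "chr1", "+", list(c(100, 200), c(500, 700))))
  expect_equal(nrow(ann$introns), 1)
  expect_equal(ann$introns$start, 200)
  expect_equal(ann$introns$end, 500)
  expect_equal(ann$introns$length, 300)
  expect_equal(ann$introns$sa_pos, 500)
  expect_equal(ann$last_exons$start, 500)

  # same exons on minus strand: SA flips to the genomic-left exon (pos 199)
  annm <- read_gtf_fixture(
    gtf_gene("gm", "chr1", "-", list(c(100, 200), c(500, 700))))
  expect_equal(annm$introns$sa_pos, 199)
  expect_equal(annm$last_exons$start, 100)
  expect_equal(annm$genes$tss, 699)
  expect_equal(annm$genes$pas, 100)
})

test_that("single-exon genes yield no introns and are their own last exon", {
  ann <- read_gtf_fixture(gtf_gene("gs", "chr2", "+", list(c(10, 400))))
  expect_equal(nrow(ann$introns), 0)
  expect_equal(ann$last_exons$start, 10)
  expect_equal(ann$last_exons$end, 400)
})

test_that("overlapping exons are rejected, unknown biotypes default", {
  bad <- gtf_gene("gx", "chr1", "+", list(c(100, 300), c(250, 400)))
  expect_error(read_gtf_fixture(bad), "overlap")
  ann <- read_gtf_fixture(
    gtf_gene("gy", "chr1", "+", list(c(0, 50)), biotype = "misc_RNA"))
  expect_equal(ann$genes$biotype, "not_annotated")
})

test_that("snoRNA genes inside introns flag their host introns", {
  ann <- read_gtf_fixture(
    gtf_gene("host", "chr1", "+", list(c(0, 100), c(1000, 1200))),
    gtf_gene("sno", "chr1", "+", list(c(400, 520)), biotype = "snoRNA"))
  expect_true(ann$introns$snoRNA_hosting)
  expect_equal(ann$introns$sno_start, 400)
  # opposite-strand snoRNA must not flag the intron
  ann2 <- read_gtf_fixture(
    gtf_gene("host", "chr1", "+", list(c(0, 100), c(1000, 1200))),
    gtf_gene("sno", "chr1", "-", list(c(400, 520)), biotype = "snoRNA"))
  expect_false(ann2$introns$snoRNA_hosting)
})

test_that("annotation GTF round-trip preserves the derived model", {
  cfg <- sim_config(seed = 3, n_genes = 6, n_lncrna = 2, n_ernas = 3)
  ann <- simulate_annotation(cfg)
  f <- tempfile(fileext = ".gtf")
  write_annotation(ann, f)
  ann2 <- read_annotation(f)
  for (part in c("genes", "exons", "introns", "last_exons")) {
    a <- ann[[part]][do.call(order, ann[[part]]), ]
    b <- ann2[[part]][do.call(order, ann2[[part]]), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, info = part)
  }
})

test_that("overlap_any matches half-open, strand-specific semantics", {
  q <- genomic_interval("chr1", 10, 20, "+")
  expect_equal(nrow(overlap_any(q, genomic_interval("chr1", 20, 30, "+"))), 0)
  expect_equal(nrow(overlap_any(q, genomic_interval("chr1", 19, 30, "+"))), 1)
  expect_equal(nrow(overlap_any(q, genomic_interval("chr1", 10, 20, "-"))), 0)
})

test_that("overlap_any equals brute-force per-nucleotide sets on random instances", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      mk <- function(n) {
        s <- sample.int(9900, n)
        genomic_interval(sample(c("cA", "cB"), n, TRUE), s,
                         s + sample.int(100, n, TRUE),
                         sample(c("+", "-"), n, TRUE))
      }
      q <- mk(8); s <- mk(12)
    })
    got <- overlap_any(q, s)
    want <- bf_overlap(q, s)
    o <- function(d) d[order(d$query, d$subject), , drop = FALSE]
    expect_equal(unname(as.matrix(o(got))), unname(as.matrix(o(want))))
  }
})

test_that("bedGraph read handles empty files and single positions", {
  f <- tempfile(fileext = ".bedgraph")
  file.create(f)
  tr <- read_endtrack(f, "+")
  expect_equal(nrow(tr$counts), 0)
  expect_equal(track_total(tr), 0)

  writeLines("chr1\t10\t11\t5", f)
  tr <- read_endtrack(f, "+")
  expect_equal(tr$counts$pos, 10)
  expect_equal(tr$counts$value, 5)

  writeLines("chr1\t10\t12\t-3", f)
  expect_error(read_endtrack(f, "+"), "negative")
})

test_that("bedGraph write/read round-trips random sparse tracks", {
  for (seed in c(2, 7, 19)) {
    tr <- random_track(seed)
    prefix <- tempfile()
    write_endtrack(tr, prefix)
    tr2 <- read_endtrack_pair(prefix, library_id = tr$library_id)
    expect_equal(as.data.frame(tr$counts), as.data.frame(tr2$counts))
    # second write of the re-read track is byte-identical (canonical form)
    prefix2 <- tempfile()
    write_endtrack(tr2, prefix2)
    expect_identical(readLines(paste0(prefix, ".plus.bedgraph")),
                     readLines(paste0(prefix2, ".plus.bedgraph")))
    expect_identical(readLines(paste0(prefix, ".minus.bedgraph")),
                     readLines(paste0(prefix2, ".minus.bedgraph")))
  }
})

test_that("run-length encoding on write expands back to per-position values", {
  tr <- end_track(data.frame(chrom = "chr1", strand = "+",
                             pos = c(5L, 6L, 7L, 9L), value = c(2, 2, 2, 1)))
  prefix <- tempfile()
  write_endtrack(tr, prefix)
  lines <- readLines(paste0(prefix, ".plus.bedgraph"))
  expect_equal(length(lines), 2)   # one merged run [5,8) plus [9,10)
  tr2 <- read_endtrack(paste0(prefix, ".plus.bedgraph"), "+")
  expect_equal(tr2$counts$pos, c(5L, 6L, 7L, 9L))
  expect_equal(tr2$counts$value, c(2, 2, 2, 1))
})
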