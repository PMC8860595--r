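test_that("sensitivity reproduces its boundary values and simple ratios", {
  expect_equal(sensitivity(37, 0), 1)
  expect_equal(sensitivity(250, 0), 1)
  expect_equal(sensitivity(58, 58), 0)
  expect_equal(sensitivity(0.3, 0.3), 0)
  expect_equal(sensitivity(0, 12), -1)
  expect_equal(sensitivity(3, 1), 2 / 3)
  expect_equal(sensitivity(0.4, 0), 0.4)   # unit floor binds below 1
  expect_error(sensitivity(-1, 2), "non-negative")
})

test_that("sensitivity is bounded, antisymmetric and scale-invariant above 1", {
  withr::with_seed(77, {
    tr <- runif(10000, 0, 1000); ct <- runif(10000, 0, 1000)
  })
  s <- sensitivity(tr, ct)
  expect_lte(max(abs(s)), 1)
  # antisymmetry for arguments >= 1
  a <- tr + 1; b <- ct + 1
  expect_equal(sensitivity(a, b), -sensitivity(b, a))
  # scale invariance on a grid with c >= 1
  g <- expand.grid(a = c(1, 3.7, 40, 1000), b = c(1, 12, 500, 1000),
                   c = c(1, 2.5, 100))
  expect_equal(sensitivity(g$a * g$c, g$b * g$c), sensitivity(g$a, g$b))
})

test_that("sensitivity_matrix averages replicates and hits planted values", {
  m <- rbind(c1 = c(10, 14, 40, 44), c2 = c(20, 20, 20, 20))
  colnames(m) <- c("r1", "r2", "t1", "t2")
  sm <- sensitivity_matrix(m, list(
    up = list(treated = c("t1", "t2"), ref = c("r1", "r2")),
    self = list(treated = c("r1", "r2"), ref = c("r1", "r2"))))
  expect_equal(sm["c1", "up"], (42 - 12) / 42)
  expect_equal(sm["c2", "up"], 0)
  expect_equal(unname(sm[, "self"]), c(0, 0))
  expect_error(sensitivity_matrix(m, list(x = list(treated = character(0),
                                                   ref = "r1"))), "empty")
  # planted fourfold effect at high expression approaches 0.75
  fx <- pipeline_fixture()
  truth <- fx$truth
  map <- setNames(fx$truth_match$cluster_id, fx$truth_match$truth_id)
  nxt <- truth$cluster_id[truth$pathway == "NEXT" & truth$base_mean > 50 &
                          !truth$trimming_target]
  ids <- stats::na.omit(map[nxt])
  col <- fx$sensitivity[ids, "AID_ZCCHC8_6h_pAall"]
  expect_equal(median(col), 0.75, tolerance = 0.12)
  expect_true(all(abs(fx$sensitivity) <= 1))
})

test_that("classification intersects methods and enforces mutual exclusion", {
  cls <- classify_targets(c("a", "b", "c"), c("b", "c", "d"),
                          c("c", "e"), c("c", "e", "f"))
  expect_setequal(cls$NEXT, "b")        # c is in both candidate sets
  expect_setequal(cls$PAXT, "e")
  expect_length(intersect(cls$NEXT, cls$PAXT), 0)
  # disjoint candidates pass through unchanged
  cls2 <- classify_targets("a", "a", "b", "b")
  expect_equal(cls2$NEXT, "a"); expect_equal(cls2$PAXT, "b")
  # RNAi-only mode ignores the AID sets
  cls3 <- classify_targets(c("a", "x"), character(0), c("b", "x"),
                           character(0), mode = "RNAi")
  expect_setequal(cls3$NEXT, "a"); expect_setequal(cls3$PAXT, "b")
  # fuzz: classes are disjoint on random inputs
  for (seed in 1:10) {
    ss <- withr::with_seed(seed, replicate(4, sample(letters, sample(5:15, 1)),
                                           simplify = FALSE))
    cl <- classify_targets(ss[[1]], ss[[2]], ss[[3]], ss[[4]])
    expect_length(intersect(cl$NEXT, cl$PAXT), 0)
  }
})

test_that("composition percentages are well-formed", {
  ca <- data.frame(cluster_id = c("a", "b", "c", "d"),
                   biotype = c("PROMPT", "PROMPT", "eRNA", NA),
                   feature = NA_character_)
  comp <- composition(c("a", "b", "c", "d"), ca, "biotype")
  expect_equal(comp[["PROMPT"]], 50)
  expect_equal(comp[["eRNA"]], 25)
  expect_equal(comp[["not_annotated"]], 25)
  expect_equal(sum(comp), 100)
  expect_equal(unname(composition("a", ca, "biotype")), 100)
  expect_warning(empty <- composition(character(0), ca, "biotype"), "empty")
  expect_length(empty, 0)
  for (seed in 1:5) {
    mem <- withr::with_seed(seed, sample(c("a", "b", "c"), sample(1:3, 1)))
    expect_equal(sum(composition(mem, ca, "biotype")), 100)
  }
})

test_that("intron length classes use the published boundaries", {
  expect_equal(intron_length_class(c(1, 699, 700, 4000, 4001, 99999)),
               c("short", "short", "medium", "medium", "long", "long"))
  expect_error(intron_length_class(0), "positive")
})

test_that("SA overlap fractions hit the trivial extremes", {
  anchors <- data.frame(chrom = "c", pos = c(100, 5000, 9000), strand = "+",
                        intron_length = c(300, 2000, 8000),
                        length_class = c("short", "medium", "long"),
                        snoRNA_hosting = FALSE)
  clusters <- data.frame(cluster_id = c("x", "y", "z"), chrom = "c",
                         start = c(95, 4995, 8995), end = c(100, 5000, 9000),
                         strand = "+", summit = c(99, 4999, 8999),
                         pooled_count = 10)
  none <- sa_overlap_fraction(anchors, list(cond = character(0)), clusters)
  expect_equal(none$fraction, c(0, 0, 0))
  all_up <- sa_overlap_fraction(anchors, list(cond = c("x", "y", "z")),
                                clusters)
  expect_equal(all_up$fraction, c(100, 100, 100))
  # empty stratum yields NA
  sub <- sa_overlap_fraction(anchors[1, ], list(cond = "x"), clusters)
  expect_true(is.na(sub$fraction[sub$length_class == "long"]))
  # expressed denominator drops uncovered anchors
  far <- rbind(anchors, data.frame(chrom = "c", pos = 20000, strand = "+",
                                   intron_length = 9000,
                                   length_class = "long",
                                   snoRNA_hosting = FALSE))
  ex <- sa_overlap_fraction(far, list(cond = c("x", "y", "z")), clusters,
                            denominator = "expressed")
  expect_equal(ex$fraction[ex$length_class == "long"], 100)
})

test_that("planted length-scaled RNAi effects produce the stratified gradient", {
  fx <- pipeline_fixture()
  tab <- fx$sa_overlap
  get <- function(cond) {
    sub <- tab[tab$condition == cond, ]
    setNames(sub$fraction, sub$length_class)[c("short", "medium", "long")]
  }
  rnai <- get("RNAi_ZCCHC8_pAall")
  aid2 <- get("AID_ZCCHC8_2h_pAall")
  expect_true(rnai[["short"]] < rnai[["medium"]])
  expect_true(rnai[["medium"]] < rnai[["long"]])
  expect_lte(max(aid2) - min(aid2), 5)
})
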