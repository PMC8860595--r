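unit_sf <- function(counts) setNames(rep(1, ncol(counts)), colnames(counts))

test_that("dispersion estimator recovers planted values and floors constants", {
  # Poisson data: estimates collapse toward zero
  simp <- simulate_cluster_counts(300, c(a = 50, b = 50), 0, alpha = 0,
                                  seed = 61)
  ap <- estimate_dispersion(simp$counts, unit_sf(simp$counts),
                            simp$condition)
  expect_lte(median(ap), 0.01)
  # alpha = 0.2 recovered within +-50% at n = 20, mu >= 100
  sim2 <- simulate_cluster_counts(300, c(a = 20, b = 20), 0, alpha = 0.2,
                                  mu_log = log(300), sdlog = 0.3, seed = 62)
  a2 <- estimate_dispersion(sim2$counts, unit_sf(sim2$counts),
                            sim2$condition)
  expect_gt(median(a2), 0.1)
  expect_lt(median(a2), 0.3)
  # constant counts hit the floor
  m <- matrix(7L, nrow = 3, ncol = 4,
              dimnames = list(letters[1:3], paste0("L", 1:4)))
  ac <- estimate_dispersion(m, unit_sf(m), rep(c("a", "b"), each = 2))
  expect_equal(unname(ac), rep(1e-6, 3))
})

test_that("nb_wald is near-null calibrated and recovers planted effects", {
  sim <- simulate_cluster_counts(800, c(ref = 2, treated = 2), 0, seed = 63)
  de <- nb_wald(sim$counts, unit_sf(sim$counts), sim$condition)
  expect_lt(abs(mean(de$log2FC, na.rm = TRUE)), 0.05)
  expect_lt(mean(de$pvalue < 0.05, na.rm = TRUE), 0.09)
  # p-values roughly uniform: quartiles near (0.25, 0.5, 0.75)
  qs <- quantile(de$pvalue, c(0.25, 0.5, 0.75), na.rm = TRUE)
  expect_equal(unname(qs), c(0.25, 0.5, 0.75), tolerance = 0.15)
  # planted 4-fold effect at mu = 200: mean estimate within 2 +- 0.3
  sim4 <- simulate_cluster_counts(500, c(ref = 2, treated = 2), 2,
                                  mu_log = log(200), sdlog = 0, seed = 64)
  de4 <- nb_wald(sim4$counts, unit_sf(sim4$counts), sim4$condition)
  expect_equal(mean(de4$log2FC, na.rm = TRUE), 2, tolerance = 0.15)
})

test_that("log2FC is invariant to doubling counts together with size factors", {
  sim <- simulate_cluster_counts(100, c(ref = 2, treated = 2), 1, seed = 65)
  sf1 <- unit_sf(sim$counts)
  disp <- estimate_dispersion(sim$counts, sf1, sim$condition)
  de1 <- nb_wald(sim$counts, sf1, sim$condition, dispersions = disp)
  de2 <- nb_wald(sim$counts * 2L, sf1 * 2, sim$condition, dispersions = disp)
  expect_equal(de1$log2FC, de2$log2FC, tolerance = 1e-6)
})

test_that("batch covariate absorbs a planted batch offset", {
  withr::with_seed(66, {
    mu <- rlnorm(300, log(200), 0.4)
    batch_eff <- 2     # batch 2 libraries doubled across the board
    k <- cbind(
      r1 = rnbinom(300, mu = mu, size = 20),
      r2 = rnbinom(300, mu = mu * batch_eff, size = 20),
      t1 = rnbinom(300, mu = mu, size = 20),
      t2 = rnbinom(300, mu = mu * batch_eff, size = 20))
  })
  rownames(k) <- sprintf("c%03d", 1:300)
  cond <- c("ref", "ref", "treated", "treated")
  batch <- c("b1", "b2", "b1", "b2")
  de <- nb_wald(k, unit_sf(k), cond, batch = batch)
  expect_lt(abs(mean(de$log2FC, na.rm = TRUE)), 0.1)
  expect_lt(mean(de$pvalue < 0.05, na.rm = TRUE), 0.1)
})

test_that("BH adjustment matches the sorted-formula oracle and handles NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(50)^2)
    expect_equal(bh_adjust(p), bf_bh(p))
  }
  p <- c(0.01, NA, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bf_bh(p[c(1, 3)]))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("upregulation thresholds are strict on both axes", {
  res <- data.frame(cluster_id = c("a", "b", "c", "d"),
                    log2FC = c(1.0, 2, 2, 2),
                    padj = c(0.01, 0.05, 0.1, NA))
  expect_equal(call_upregulated(res), "b")   # a: lfc not > 1; c: padj not < 0.1
  expect_setequal(call_upregulated(res, lfc_min = 0.5, padj_max = 0.2),
                  c("a", "b", "c"))
})

test_that("PCA uses available clusters, duplicates coincide, conditions separate", {
  fx <- sim_fixture()
  sf <- fx$sf
  pc <- pca_top_variance(fx$counts, sf, n_top = 2000)
  expect_equal(attr(pc, "n_used"), nrow(fx$counts))   # fewer than 2000
  # duplicated library lands on identical coordinates
  counts2 <- cbind(fx$counts, dup = fx$counts[, 1])
  sf2 <- c(sf, dup = unname(sf[colnames(fx$counts)[1]]))
  pc2 <- pca_top_variance(counts2, sf2, 50)
  i <- match(colnames(fx$counts)[1], pc2$library_id)
  j <- match("dup", pc2$library_id)
  expect_equal(pc2[i, c("PC1", "PC2")], pc2[j, c("PC1", "PC2")],
               ignore_attr = TRUE)
  # ZCCHC8 6 h and ZFC3H1 6 h separate (positive silhouette on PC1/PC2)
  d6 <- fx$design[fx$design$method == "AID" & fx$design$timepoint_h == 6, ]
  sub <- pc[pc$library_id %in% d6$library_id, ]
  grp <- d6$target[match(sub$library_id, d6$library_id)]
  X <- as.matrix(sub[, c("PC1", "PC2")])
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- grp == grp[i]; own[i] <- FALSE
    a <- mean(sqrt(rowSums((X[own, , drop = FALSE] -
                            rep(X[i, ], each = sum(own)))^2)))
    b <- mean(sqrt(rowSums((X[!(grp == grp[i]), , drop = FALSE] -
                            rep(X[i, ], each = sum(grp != grp[i])))^2)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_error(pca_top_variance(fx$counts[, 1:2], sf[1:2]), ">= 3")
})
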