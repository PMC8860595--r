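# Negative-binomial differential expression of cluster counts.  Dispersion
# follows the variance = mu + alpha * mu^2 parameterization.  Per-cluster
# alpha comes from a pooled within-group method-of-moments estimate shrunk
# toward a mean-dependent trend with a fixed weight, then each cluster is
# fit with a log-link NB GLM at fixed dispersion and tested by Wald.

ALPHA_FLOOR <- 1e-6

#' Per-cluster dispersion estimates
#'
#' Method-of-moments on size-factor-normalized counts, pooled within design
#' groups so condition effects do not inflate the estimate:
#' `alpha_raw = max(0, sum_g (n_g - 1) (s2_g - m_g) / sum_g (n_g - 1) m_g^2)`.
#' Raw estimates are shrunk toward a fitted mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` with a fixed weight, and floored at `1e-6`.
#'
#' @param counts Integer matrix, cluster x library.
#' @param sf Named size factors covering every column.
#' @param group Factor/character vector of design groups per library; at
#'   least one group needs >= 2 replicates.
#' @param shrink_weight Weight on the trend value in `[0, 1]`; default 0.85
#'   (a heavy trend weight suits the small replicate numbers of typical
#'   3' end seq designs, where the per-cluster moment estimate is noisy).
#' @return Numeric vector of per-cluster dispersions.
#' @export
estimate_dispersion <- function(counts, sf, group, shrink_weight = 0.85) {
  if (ncol(counts) < 2) stop("dispersion estimation needs >= 2 libraries")
  group <- as.factor(group)
  if (!any(table(group) >= 2))
    stop("no design group with >= 2 replicates")
  q <- normalize_counts(counts, sf)
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  mu_bar <- rowMeans(q)
  for (g in levels(group)) {
    idx <- which(group == g)
    if (length(idx) < 2) next
    qg <- q[, idx, drop = FALSE]
    m <- rowMeans(qg)
    s2 <- apply(qg, 1, var)
    w <- length(idx) - 1
    num <- num + w * (s2 - m)
    den <- den + w * m^2
  }
  alpha_raw <- pmax(0, ifelse(den > 0, num / den, 0))
  alpha_trend <- fit_dispersion_trend(mu_bar, alpha_raw)
  alpha <- (1 - shrink_weight) * alpha_raw + shrink_weight * alpha_trend
  pmax(alpha, ALPHA_FLOOR)
}

# robust fit of alpha(mu) = a0 + a1/mu on positive raw estimates; falls back
# to the mean raw estimate when too few informative clusters exist
fit_dispersion_trend <- function(mu, alpha_raw) {
  ok <- is.finite(mu) & mu > 0 & is.finite(alpha_raw)
  if (sum(ok & alpha_raw > 0) >= 10) {
    fit <- try(stats::lm(alpha_raw[ok] ~ I(1 / mu[ok])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      a <- coef(fit)
      a0 <- max(0, a[1]); a1 <- max(0, a[2])
      tr <- a0 + a1 / pmax(mu, 1e-8)
      return(pmax(tr, ALPHA_FLOOR))
    }
  }
  rep(max(mean(alpha_raw[ok]), ALPHA_FLOOR), length(mu))
}

#' Negative-binomial Wald test per cluster
#'
#' Fits, per cluster, `count ~ condition (+ batch)` with a log-link NB GLM
#' at fixed per-cluster dispersion, using `log(size factor)` offsets, and
#' reports the Wald test of the treated-vs-reference coefficient.
#' Non-converged fits yield `NA` p-values (excluded from BH) rather than
#' errors.
#'
#' @param counts Integer matrix cluster x library.
#' @param sf Named size factors.
#' @param condition Character/factor per library with exactly two levels;
#'   the first level (or `ref`) is the reference.
#' @param ref Reference level; default the first factor level.
#' @param batch Optional per-library batch covariate (character/factor).
#' @param dispersions Optional per-cluster alpha vector; estimated from the
#'   condition groups when `NULL`.
#' @return data.frame `cluster_id`, `baseMean` (mean of normalized counts),
#'   `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj` (BH over non-NA p).
#' @export
nb_wald <- function(counts, sf, condition, ref = NULL, batch = NULL,
                    dispersions = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2)
    stop("nb_wald expects exactly two condition levels")
  if (!is.null(ref)) condition <- stats::relevel(condition, ref = ref)
  if (any(table(condition) == 0)) stop("empty contrast group")
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, sf, condition)
  sfv <- sf[colnames(counts)]
  q <- normalize_counts(counts, sf)
  has_batch <- !is.null(batch) && length(unique(batch)) > 1
  bf <- if (has_batch) as.factor(batch) else NULL

  n <- nrow(counts)
  log2fc <- se <- pval <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- counts[i, ]
    theta <- 1 / max(dispersions[i], ALPHA_FLOOR)
    fit <- try(suppressWarnings({
      if (has_batch)
        glm(k ~ condition + bf, offset = log(sfv),
            family = MASS::negative.binomial(theta = theta, link = "log"))
      else
        glm(k ~ condition, offset = log(sfv),
            family = MASS::negative.binomial(theta = theta, link = "log"))
    }), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) next
    # dispersion = 1: the NB family variance mu + alpha mu^2 already carries
    # the overdispersion; summary.glm would otherwise rescale by a
    # residual-based quasi-dispersion, degenerate at n = 2 per group
    sm <- summary(fit, dispersion = 1)$coefficients
    co <- grep("^condition", rownames(sm))
    if (length(co) != 1) next
    b <- sm[co, "Estimate"]; s <- sm[co, "Std. Error"]
    if (!is.finite(b) || !is.finite(s) || s <= 0 || abs(b) > 30) next
    log2fc[i] <- b / log(2)
    se[i] <- s / log(2)
    pval[i] <- 2 * pnorm(-abs(b / s))
  }
  data.frame(
    cluster_id = rownames(counts) %||% as.character(seq_len(n)),
    baseMean = rowMeans(q),
    log2FC = log2fc, lfcSE = se, stat = log2fc / se,
    pvalue = pval, padj = bh_adjust(pval),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH over the non-`NA` p-values (`NA`s stay `NA` and do not count
#' toward `m`), via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`, `NA`s allowed.
#' @return Vector of adjusted p-values, same length/order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Upregulated cluster calls
#'
#' Strict thresholds on both axes: `log2FC > lfc_min` and
#' `padj < padj_max` (a cluster at exactly either boundary is excluded).
#'
#' @param results data.frame from [nb_wald()].
#' @param lfc_min log2 fold-change threshold; default 1.
#' @param padj_max Adjusted-p threshold; default 0.1.
#' @return Character vector of `cluster_id`s.
#' @export
call_upregulated <- function(results, lfc_min = 1, padj_max = 0.1) {
  ok <- !is.na(results$log2FC) & !is.na(results$padj) &
    results$log2FC > lfc_min & results$padj < padj_max
  results$cluster_id[ok]
}

#' PCA on top-variance clusters
#'
#' Transforms normalized counts with `log2(x + 1)` (a fixed, fully specified
#' stand-in for a variance stabilizing transformation), ranks clusters by
#' variance across libraries, keeps the top `n_top`, centers per cluster and
#' computes principal components by singular value decomposition.
#'
#' @param counts Raw count matrix cluster x library (>= 3 libraries).
#' @param sf Named size factors.
#' @param n_top Number of top-variance clusters; default 2000 (capped at the
#'   number of clusters).
#' @return data.frame `library_id`, `PC1`, `PC2`, with attribute
#'   `var_explained` (fractions per component) and `n_used`.
#' @export
pca_top_variance <- function(counts, sf, n_top = 2000) {
  if (ncol(counts) < 3) stop("PCA needs >= 3 libraries")
  x <- log2(normalize_counts(counts, sf) + 1)
  v <- apply(x, 1, var)
  if (all(v == 0)) stop("zero-variance matrix; PCA undefined")
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(x)))]
  xc <- x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])
  sv <- svd(t(xc))
  pcs <- sv$u %*% diag(sv$d)
  ve <- sv$d^2 / sum(sv$d^2)
  out <- data.frame(library_id = colnames(counts),
                    PC1 = pcs[, 1], PC2 = pcs[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "var_explained") <- ve
  attr(out, "n_used") <- length(keep)
  out
}
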