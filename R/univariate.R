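# PCA and per-metabolite differential statistics for the early-vs-late
# (period A vs C) comparison: log2 fold change, Cohen's d, one-way ANOVA
# F, BH-FDR, random-forest importance, and the VIP-filtered differential
# table.

#' Principal component analysis of a Z-score matrix
#'
#' Singular value decomposition of the column-centred matrix. Variance
#' fractions are `sigma_i^2 / total variance`; each component's sign is
#' fixed so the largest-magnitude loading entry is positive, making results
#' reproducible across SVD implementations.
#'
#' @param z samples x metabolites matrix (typically [zScores()] output).
#' @param k number of leading components (1 <= k <= rank).
#' @return a [PcaResult-class].
#' @export
runPCA <- function(z, k = 2L) {
  z <- as.matrix(z)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  pr <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-12)
  if (k > rank) stop(sprintf("'k' (%d) exceeds the matrix rank (%d)", k, rank))
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  methods::new("PcaResult", scores = scores, loadings = loadings,
               varianceExplained = ve[seq_len(k)])
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values in \[0, 1\].
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bhFDR <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-metabolite differential statistics between two periods
#'
#' For every metabolite: `log2_fc = log2(mean_A / mean_C)` on the
#' (TIC-normalized, unstandardized) intensities; Cohen's d
#' `(mean_A - mean_C) / pooled SD` (invariant to per-metabolite linear
#' scaling, so identical on raw and Z-scored values); one-way ANOVA F
#' between the two groups with its p-value; and BH-FDR over all
#' metabolites tested. A non-positive group mean leaves `log2_fc` missing
#' with a warning.
#'
#' @param x samples x metabolites matrix of normalized intensities.
#' @param y two-class labels (e.g. "A"/"C"), one per sample; the
#'   alphabetically first class plays the "A" role in A-over-C quantities.
#' @return data.frame with columns `metabolite`, `log2_fc`, `cohen_d`,
#'   `f_ratio`, `p_value`, `fdr`, `enriched_period`.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4, 5, 6))
#' univariateStats(m, rep(c("A", "C"), each = 3))
#' @export
univariateStats <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("exactly two groups are required")
  iA <- y == lev[1]
  iC <- y == lev[2]
  if (sum(iA) < 2L || sum(iC) < 2L) stop("both groups need >= 2 samples")
  nA <- sum(iA)
  nC <- sum(iC)
  meanA <- colMeans(x[iA, , drop = FALSE])
  meanC <- colMeans(x[iC, , drop = FALSE])
  varA <- apply(x[iA, , drop = FALSE], 2, stats::var)
  varC <- apply(x[iC, , drop = FALSE], 2, stats::var)
  pooled <- sqrt(((nA - 1) * varA + (nC - 1) * varC) / (nA + nC - 2))
  d <- (meanA - meanC) / pooled
  badFc <- meanA <= 0 | meanC <= 0
  if (any(badFc)) {
    warning(sprintf("non-positive group mean; log2_fc missing for: %s",
                    paste(colnames(x)[badFc], collapse = ", ")))
  }
  log2fc <- ifelse(badFc, NA_real_, log2(meanA / meanC))
  # two groups: one-way ANOVA F equals the pooled-variance t statistic squared
  se2 <- pooled^2 * (1 / nA + 1 / nC)
  f <- (meanA - meanC)^2 / se2
  p <- stats::pf(f, 1, nA + nC - 2, lower.tail = FALSE)
  data.frame(
    metabolite = colnames(x),
    log2_fc = unname(log2fc), cohen_d = unname(d), f_ratio = unname(f),
    p_value = unname(p), fdr = unname(bhFDR(p)),
    enriched_period = unname(ifelse(d > 0, lev[1], lev[2])),
    stringsAsFactors = FALSE
  )
}

#' Random-forest Gini importance for the two-period classification
#'
#' Mean decrease in Gini impurity from a random forest classifying the two
#' periods, reproducible from `seed`. Delegates the ensemble to the
#' randomForest package.
#'
#' @param x samples x metabolites matrix.
#' @param y two-class labels.
#' @param nTrees number of trees (>= 1; default 500).
#' @param seed integer seed.
#' @return named numeric vector of non-negative importances.
#' @export
rfImportance <- function(x, y, nTrees = 500L, seed = 1L) {
  if (nTrees < 1L) stop("'nTrees' must be >= 1")
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("both classes must be present")
  x <- as.data.frame(as.matrix(x))
  fit <- withSeed(seed, {
    randomForest::randomForest(x, y, ntree = as.integer(nTrees))
  })
  imp <- fit$importance[, "MeanDecreaseGini"]
  stats::setNames(as.numeric(imp), rownames(fit$importance))
}

#' Differential table of VIP-selected metabolites
#'
#' Combines O-PLS-DA VIP scores, univariate statistics and random-forest
#' importance into one record per metabolite, keeps metabolites with
#' VIP > `vipCutoff`, and sorts by VIP descending. The enriched period
#' follows the sign of Cohen's d under the +1 = first-class coding.
#'
#' @param vip named VIP vector (see [vipScores()]).
#' @param stats data.frame from [univariateStats()].
#' @param importance named importance vector (see [rfImportance()]);
#'   optional.
#' @param vipCutoff VIP threshold (default 1).
#' @return data.frame with columns `metabolite`, `enriched_period`, `vip`,
#'   `log2_fc`, `fdr`, `cohen_d`, `rf_importance`, `f_ratio`, sorted by
#'   `vip` descending (possibly zero rows).
#' @export
differentialTable <- function(vip, stats, importance = NULL, vipCutoff = 1) {
  if (!setequal(names(vip), stats$metabolite)) {
    stop("VIP scores and univariate statistics cover different metabolites")
  }
  if (!is.null(importance) && !setequal(names(importance), stats$metabolite)) {
    stop("importance values cover a different metabolite set")
  }
  out <- data.frame(
    metabolite = stats$metabolite,
    enriched_period = stats$enriched_period,
    vip = unname(vip[stats$metabolite]),
    log2_fc = stats$log2_fc,
    fdr = stats$fdr,
    cohen_d = stats$cohen_d,
    rf_importance = if (is.null(importance)) NA_real_ else
      unname(importance[stats$metabolite]),
    f_ratio = stats$f_ratio,
    stringsAsFactors = FALSE
  )
  out <- out[out$vip > vipCutoff, , drop = FALSE]
  out <- out[order(-out$vip), , drop = FALSE]
  rownames(out) <- NULL
  out
}
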