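# PCA, O-PLS-DA fitting/validation, and per-metabolite statistics.

test_that("PCA handles rank-1 data, reconstructs, and fixes signs", {
  # variation along a single axis
  set.seed(2)
  t1 <- rnorm(10)
  v <- c(1, -2, 0.5)
  x1 <- outer(t1, v)
  colnames(x1) <- c("a", "b", "c")
  res <- runPCA(x1, k = 1)
  expect_equal(res@varianceExplained[1], 1, tolerance = 1e-12)
  expect_gt(res@loadings[which.max(abs(res@loadings[, 1])), 1], 0)

  # full-rank reconstruction of the centred matrix
  x <- randomMatrix(6, 4, seed = 5)
  res <- runPCA(x, k = 4)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(unname(res@scores %*% t(res@loadings)), unname(xc),
               tolerance = 1e-10)
  expect_error(runPCA(x, k = 0), ">= 1")
  expect_error(runPCA(x1, k = 3), "rank")
})

test_that("PCA on planted data orders periods along PC1 and loads the planted metabolites", {
  # isolate the planted day gradient: no cliques/xenometabolites, log scale
  cfg <- syntheticConfig(nMetabolites = 60, coreCliques = list(),
                         xenoNames = character(0), seed = 19)
  study <- generateStudy(cfg)
  z <- zScores(log(metaboliteMatrix(study$experiment)))
  res <- runPCA(z, k = 2)
  scoreByPeriod <- tapply(res@scores[, 1], periodLabels(study$experiment), mean)
  ord <- scoreByPeriod[c("A", "B", "C")]
  expect_true(all(diff(ord) > 0) || all(diff(ord) < 0))
  top <- names(sort(abs(res@loadings[, 1]), decreasing = TRUE))[1:20]
  expect_true(all(study$truth$differential %in% top))
})

test_that("O-PLS-DA separates a perfect signal and rejects degenerate input", {
  set.seed(4)
  y <- rep(c("A", "C"), each = 20)
  x <- cbind(sig = ifelse(y == "A", 1, -1), randomMatrix(40, 5))
  fit <- fitOplsda(x, y, nOrtho = 1)
  expect_gt(r2y(fit), 0.95)
  expect_equal(unname(predict(fit, x, type = "class")), y)
  expect_error(fitOplsda(x, rep("A", 40)), "two classes")
  expect_error(fitOplsda(x, y, nOrtho = 50), "rank")
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(12:30, 1)
    m <- sample(5:15, 1)
    x <- randomMatrix(n, m)
    y <- rep(c("A", "C"), length.out = n)
    fit <- fitOplsda(x, y, nOrtho = sample(1:2, 1))
    dots <- abs(crossprod(fit@orthoScores, fit@scores))
    lim <- 1e-6 * sqrt(colSums(fit@orthoScores^2)) * sqrt(sum(fit@scores^2))
    expect_true(all(dots <= pmax(lim, 1e-10)))
  }
})

test_that("with no orthogonal components the model is exactly PLS1", {
  set.seed(12)
  for (i in 1:5) {
    x <- randomMatrix(20, 10)
    y <- rep(c("A", "C"), each = 10)
    fit <- fitOplsda(x, y, nOrtho = 0, scaling = "center")
    yc <- ifelse(y == "A", 1, -1)
    expect_equal(unname(predict(fit, x)), unname(pls1Oracle(x, yc, x)),
                 tolerance = 1e-10)
  }
})

test_that("permuted labels give much weaker fits than true labels", {
  cfg <- syntheticConfig(days = c(4L, 6L, 18L, 20L), birdsPerDay = 10L,
                         nMetabolites = 20, effectSizeD = 2,
                         coreCliques = list(), xenoNames = character(0),
                         seed = 14)
  study <- generateStudy(cfg)
  x <- metaboliteMatrix(normalizeTIC(study$experiment))
  y <- periodLabels(study$experiment)
  obs <- r2y(fitOplsda(x, y))
  set.seed(2)
  permuted <- replicate(25, r2y(fitOplsda(x, sample(y))))
  expect_gt(obs, max(permuted))
})

test_that("VIP normalization: mean(VIP^2) = 1; symmetric cases give VIP = 1", {
  set.seed(8)
  x <- randomMatrix(16, 7)
  y <- rep(c("A", "C"), each = 8)
  v <- vipScores(fitOplsda(x, y))
  expect_equal(mean(v^2), 1, tolerance = 1e-12)

  # single metabolite: VIP forced to 1
  x1 <- randomMatrix(16, 1)
  expect_equal(unname(vipScores(fitOplsda(x1, y, nOrtho = 0))), 1)

  # exchangeable metabolites (duplicated signal column): all VIP equal 1
  sig <- ifelse(y == "A", 1, -1) + rnorm(16, 0, 0.01)
  xdup <- cbind(a = sig, b = sig, c = sig)
  vd <- vipScores(fitOplsda(xdup, y, nOrtho = 0))
  expect_equal(unname(vd), rep(1, 3), tolerance = 1e-6)
})

test_that("Q2 is high for separable data and non-positive under the null", {
  cfg <- syntheticConfig(days = c(4L, 6L, 8L, 16L, 18L, 20L), birdsPerDay = 8L,
                         nMetabolites = 20, effectSizeD = 3,
                         coreCliques = list(), xenoNames = character(0),
                         seed = 23)
  study <- generateStudy(cfg)
  x <- metaboliteMatrix(normalizeTIC(study$experiment))
  y <- periodLabels(study$experiment)
  cv <- q2CrossVal(x, y, nFolds = 10, seed = 1)
  expect_gt(cv$Q2, 0.8)
  expect_lte(cv$Q2, 1)

  # label-free data: median Q2 over null runs is not positive
  set.seed(31)
  nullQ2 <- replicate(60, {
    xn <- matrix(rnorm(40 * 10), 40, 10)
    q2CrossVal(xn, rep(c("A", "C"), each = 20), nFolds = 5,
               seed = sample.int(1e6, 1))$Q2
  })
  expect_lte(median(nullQ2), 0)
})

test_that("fold assignment is stratified, reproducible, and guards class loss", {
  y <- rep(c("A", "C"), each = 15)
  x <- randomMatrix(30, 5, seed = 3)
  cv1 <- q2CrossVal(x, y, nFolds = 5, seed = 77)
  cv2 <- q2CrossVal(x, y, nFolds = 5, seed = 77)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$Q2, cv2$Q2)
  perFold <- table(cv1$folds, y)
  expect_true(all(perFold == 3))
  expect_error(q2CrossVal(x, y, nFolds = 1), ">= 2")
})

test_that("permutation p-values follow the add-one convention", {
  # strong signal: observed beats every permutation
  set.seed(6)
  y <- rep(c("A", "C"), each = 10)
  x <- cbind(sig = ifelse(y == "A", 1, -1) + rnorm(20, 0, 0.05),
             randomMatrix(20, 4))
  pt <- permutationTest(x, y, nPerm = 99, seed = 2, computeQ2 = FALSE)
  expect_equal(pt$pR2Y, 1 / 100)
  # support bounds hold for a null fit too
  xn <- randomMatrix(20, 4, seed = 99)
  ptn <- permutationTest(xn, y, nPerm = 19, seed = 3, computeQ2 = FALSE)
  expect_gte(ptn$pR2Y, 1 / 20)
  expect_lte(ptn$pR2Y, 1)
})

test_that("CV-ANOVA matches direct arithmetic and flags perfect separation", {
  pred <- c(1.0, 0.8, 1.2, -1.1, -0.9, -1.0)
  y <- rep(c("A", "C"), each = 3)
  res <- cvAnova(pred, y)
  # direct evaluation of the one-way ANOVA decomposition
  grand <- mean(pred)
  mA <- mean(pred[1:3]); mC <- mean(pred[4:6])
  ssb <- 3 * (mA - grand)^2 + 3 * (mC - grand)^2
  ssw <- sum((pred[1:3] - mA)^2) + sum((pred[4:6] - mC)^2)
  expect_equal(res$F, (ssb / 1) / (ssw / 4))
  expect_equal(res$p, pf(res$F, 1, 4, lower.tail = FALSE))
  expect_equal(res$eta2, ssb / (ssb + ssw))
  # cross-check against base R's ANOVA table
  a <- anova(lm(pred ~ y))
  expect_equal(res$F, a$`F value`[1])
  expect_equal(res$p, a$`Pr(>F)`[1])

  expect_warning(perfect <- cvAnova(c(1, 1, 1, -1, -1, -1), y), "Inf")
  expect_equal(perfect$eta2, 1)
  expect_equal(perfect$p, 0)
})

test_that("univariate statistics match hand arithmetic", {
  m <- cbind(met = c(1, 2, 3, 4, 5, 6))
  y <- rep(c("A", "C"), each = 3)
  res <- univariateStats(m, y)
  expect_equal(res$cohen_d, -3)       # means 2 vs 5, pooled SD 1
  expect_equal(res$log2_fc, log2(2 / 5))
  expect_equal(res$enriched_period, "C")
  # F equals base R one-way ANOVA
  a <- anova(lm(m[, 1] ~ y))
  expect_equal(res$f_ratio, a$`F value`[1])
  expect_equal(res$p_value, a$`Pr(>F)`[1])

  # identical group means: null statistics
  m0 <- cbind(met = c(1, 2, 3, 1, 2, 3))
  res0 <- univariateStats(m0, y)
  expect_equal(res0$log2_fc, 0)
  expect_equal(res0$cohen_d, 0)

  # doubled mean: log2 fold change of exactly 1
  m2 <- cbind(met = c(2, 4, 6, 1, 2, 3))
  expect_equal(univariateStats(m2, y)$log2_fc, 1)

  # non-positive group mean: missing log2_fc with a warning
  mneg <- cbind(met = c(-1, 0, 1, 1, 2, 3))
  expect_warning(resn <- univariateStats(mneg, y), "met")
  expect_true(is.na(resn$log2_fc))
})

test_that("BH FDR matches the step-up examples", {
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.03), 0.03)
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("random-forest importance finds a planted separator and is reproducible", {
  set.seed(5)
  y <- rep(c("A", "C"), each = 20)
  x <- randomMatrix(40, 8)
  x[, 1] <- ifelse(y == "A", 2, -2) + rnorm(40, 0, 0.3)
  imp1 <- rfImportance(x, y, nTrees = 200, seed = 7)
  imp2 <- rfImportance(x, y, nTrees = 200, seed = 7)
  expect_identical(imp1, imp2)
  expect_equal(names(which.max(imp1)), "m01")
  expect_true(all(imp1 >= 0))
  expect_error(rfImportance(x, y, nTrees = 0), ">= 1")
})

test_that("the differential table filters by VIP, sorts, and validates inputs", {
  study <- generateStudy(syntheticConfig(seed = 3))
  x <- metaboliteMatrix(normalizeTIC(study$experiment))
  p <- periodLabels(study$experiment)
  i <- p %in% c("A", "C")
  fit <- fitOplsda(x[i, ], p[i])
  uni <- univariateStats(x[i, ], p[i])
  tab <- differentialTable(vipScores(fit), uni)
  expect_true(all(tab$vip > 1))
  expect_true(!is.unsorted(rev(tab$vip)))
  # planted group-1 metabolites (elevated early) are enriched in A
  g1 <- tab[tab$metabolite %in% study$truth$group1, ]
  expect_true(all(g1$enriched_period == "A"))
  g2 <- tab[tab$metabolite %in% study$truth$group2, ]
  expect_true(all(g2$enriched_period == "C"))

  # no VIP above the cutoff: empty table, not an error
  fake <- setNames(c(0.5, 0.9), uni$metabolite[1:2])
  empty <- differentialTable(fake, uni[1:2, ])
  expect_equal(nrow(empty), 0L)

  expect_error(differentialTable(fake, uni), "different metabolites")
})
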