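# Orthogonal partial least squares discriminant analysis (O-PLS-DA) with
# full validation: cross-validated Q2, permutation testing and CV-ANOVA.
#
# The fit follows the orthogonal-projections-to-latent-structures scheme:
# components uncorrelated with the class label are iteratively removed from
# X, after which a single predictive component is fitted. With zero
# orthogonal components the model reduces exactly to single-component PLS1.

#' @noRd
codeLabels <- function(y) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) {
    stop(sprintf("exactly two classes are required, got: %s",
                 paste(lev, collapse = ", ")))
  }
  coding <- stats::setNames(c(1, -1), lev)
  list(coded = coding[as.character(y)], coding = coding)
}

#' @noRd
scaleParams <- function(x, scaling) {
  m <- ncol(x)
  center <- if (scaling == "none") rep(0, m) else colMeans(x)
  s <- rep(1, m)
  if (scaling %in% c("uv", "pareto")) {
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1   # near-constant columns: centre only
    s <- if (scaling == "uv") sdv else sqrt(sdv)
  }
  list(center = center, scale = s)
}

#' Fit an O-PLS-DA model
#'
#' Discriminates two classes (e.g. growth periods A and C) with one
#' predictive latent component after removing `nOrtho` components of
#' X-variation orthogonal to the class label. Class coding is +1 for the
#' alphabetically first label and -1 for the second, mean-centered before
#' fitting.
#'
#' RMSEE is computed as `sqrt(SS_res / (n - 1 - a))` with `a` the total
#' number of model components (1 + `nOrtho`), the degrees-of-freedom
#' convention of the common commercial implementation.
#'
#' @param x samples x metabolites numeric matrix.
#' @param y class labels (two distinct values), one per sample.
#' @param nOrtho number of orthogonal components (>= 0, default 1).
#' @param scaling x pretreatment: `"uv"` (centre + unit variance, default),
#'   `"center"`, `"pareto"` (centre + sqrt-SD) or `"none"`.
#' @return an [OplsdaModel-class].
#' @examples
#' x <- matrix(rnorm(40 * 8), 40, 8,
#'             dimnames = list(NULL, paste0("m", 1:8)))
#' y <- rep(c("A", "C"), each = 20)
#' x[, 1] <- ifelse(y == "A", 1, -1) + rnorm(40, 0, 0.1)
#' fit <- fitOplsda(x, y, nOrtho = 1)
#' r2y(fit)
#' @export
fitOplsda <- function(x, y, nOrtho = 1L,
                      scaling = c("uv", "center", "pareto", "none")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  n <- nrow(x)
  m <- ncol(x)
  if (length(y) != n) stop("'y' must have one label per sample")
  nOrtho <- as.integer(nOrtho)
  if (nOrtho < 0L) stop("'nOrtho' must be >= 0")
  if (nOrtho >= min(n - 1L, m)) {
    stop("'nOrtho' must be smaller than the rank bound min(n - 1, m)")
  }
  cl <- codeLabels(y)
  yCenter <- mean(cl$coded)
  y0 <- cl$coded - yCenter
  sp <- scaleParams(x, scaling)
  e <- sweep(sweep(x, 2, sp$center, `-`), 2, sp$scale, `/`)

  Wo <- matrix(0, m, nOrtho)
  To <- matrix(0, n, nOrtho)
  Po <- matrix(0, m, nOrtho)
  for (k in seq_len(nOrtho)) {
    w <- drop(crossprod(e, y0))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate fit: X carries no covariance with y")
    w <- w / nw
    t <- drop(e %*% w)
    p <- drop(crossprod(e, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) {
      stop("orthogonal component exhausted the X rank; reduce 'nOrtho'")
    }
    wo <- wo / nwo
    to <- drop(e %*% wo)
    po <- drop(crossprod(e, to)) / sum(to^2)
    Wo[, k] <- wo
    To[, k] <- to
    Po[, k] <- po
    e <- e - tcrossprod(to, po)
  }
  w <- drop(crossprod(e, y0))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate fit: X carries no covariance with y")
  w <- w / nw
  t <- drop(e %*% w)
  p <- drop(crossprod(e, t)) / sum(t^2)
  cc <- sum(y0 * t) / sum(t^2)
  yhat0 <- t * cc
  ssRes <- sum((y0 - yhat0)^2)
  ssTot <- sum(y0^2)
  a <- 1L + nOrtho
  if (n - 1L - a <= 0L) stop("too few samples for the requested model size")
  model <- methods::new(
    "OplsdaModel",
    weights = stats::setNames(w, colnames(x)), scores = t,
    loadings = stats::setNames(p, colnames(x)), yLoading = cc,
    orthoWeights = Wo, orthoScores = To, orthoLoadings = Po,
    R2Y = 1 - ssRes / ssTot, RMSEE = sqrt(ssRes / (n - 1L - a)),
    coding = cl$coding,
    xCenter = sp$center, xScale = sp$scale, yCenter = yCenter,
    fitted = yhat0 + yCenter, nOrtho = nOrtho,
    featureNames = colnames(x)
  )
  methods::validObject(model)
  model
}

#' Predict coded responses or classes for new samples
#'
#' Applies the training centring/scaling, removes the orthogonal
#' components, and scores the predictive component.
#'
#' @param object an [OplsdaModel-class].
#' @param newdata samples x metabolites matrix with the training columns.
#' @param type `"response"` for numeric predictions on the coded-y scale or
#'   `"class"` for predicted labels.
#' @return numeric vector or character vector of labels.
#' @export
setMethod("predict", "OplsdaModel", function(object, newdata,
                                             type = c("response", "class")) {
  type <- match.arg(type)
  e <- as.matrix(newdata)
  if (!is.null(colnames(e))) e <- e[, object@featureNames, drop = FALSE]
  e <- sweep(sweep(e, 2, object@xCenter, `-`), 2, object@xScale, `/`)
  for (k in seq_len(object@nOrtho)) {
    to <- drop(e %*% object@orthoWeights[, k])
    e <- e - tcrossprod(to, object@orthoLoadings[, k])
  }
  yhat <- drop(e %*% object@weights) * object@yLoading + object@yCenter
  if (type == "response") return(yhat)
  pos <- names(object@coding)[object@coding > 0]
  neg <- names(object@coding)[object@coding < 0]
  ifelse(yhat >= object@yCenter, pos, neg)
})

#' Variable importance in projection (VIP)
#'
#' VIP over the single predictive component:
#' `VIP_j = sqrt(m) * |w_j|` with `w` the unit-norm predictive weight
#' vector, the single-component reduction of the usual weighted-SSY form.
#' By construction `mean(VIP^2) = 1`, so VIP > 1 marks metabolites with
#' above-average influence on the discrimination.
#'
#' @param model a fitted [OplsdaModel-class].
#' @return named numeric vector of VIP scores.
#' @export
vipScores <- function(model) {
  stopifnot(methods::is(model, "OplsdaModel"))
  sqrt(length(model@weights)) * abs(model@weights)
}

#' @noRd
stratifiedFolds <- function(y, nFolds, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  withSeed(seed, {
    for (lev in sort(unique(y))) {
      idx <- which(y == lev)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
  })
  for (f in seq_len(nFolds)) {
    if (length(unique(y[fold != f])) < 2L) {
      stop("a cross-validation fold leaves a single-class training set; ",
           "reduce 'nFolds'")
    }
  }
  fold
}

#' Cross-validated Q2
#'
#' Stratified k-fold cross-validation of the O-PLS-DA model.
#' `Q2 = 1 - PRESS / SS_total`, where PRESS accumulates squared out-of-fold
#' prediction errors of the coded label and SS_total is the total sum of
#' squares of the coded label about its mean. Fold assignment is
#' reproducible from `seed`.
#'
#' @inheritParams fitOplsda
#' @param nFolds number of folds (>= 2; default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `Q2`, `predictions` (out-of-fold coded predictions in
#'   sample order) and `folds` (fold index per sample).
#' @export
q2CrossVal <- function(x, y, nFolds = 10L, seed = 1L, nOrtho = 1L,
                       scaling = c("uv", "center", "pareto", "none")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("'nFolds' must be >= 2")
  cl <- codeLabels(y)
  fold <- stratifiedFolds(y, nFolds, seed)
  pred <- numeric(nrow(x))
  for (f in seq_len(nFolds)) {
    test <- fold == f
    if (!any(test)) next
    fit <- fitOplsda(x[!test, , drop = FALSE], y[!test],
                     nOrtho = nOrtho, scaling = scaling)
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  press <- sum((cl$coded - pred)^2)
  ssTot <- sum((cl$coded - mean(cl$coded))^2)
  list(Q2 = 1 - press / ssTot, predictions = pred, folds = fold)
}

#' Permutation test for O-PLS-DA significance
#'
#' Class labels are permuted `nPerm` times and the model refitted each
#' time; p-values use the add-one convention
#' `p = (#{permuted >= observed} + 1) / (nPerm + 1)`, so the smallest
#' attainable p is `1/(nPerm + 1)` (0.001 is reported at 999-1000
#' permutations when no permutation reaches the observed statistic).
#'
#' @inheritParams q2CrossVal
#' @param nPerm number of permutations (>= 1; default 1000).
#' @param computeQ2 also permute the cross-validated Q2 (default TRUE;
#'   substantially more work since every permutation is cross-validated).
#' @return list with `pR2Y`, `pQ2` (NA when `computeQ2 = FALSE`),
#'   `observedR2Y`, `observedQ2`, `nPerm`.
#' @export
permutationTest <- function(x, y, nPerm = 1000L, seed = 1L, nOrtho = 1L,
                            nFolds = 10L,
                            scaling = c("uv", "center", "pareto", "none"),
                            computeQ2 = TRUE) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("'nPerm' must be >= 1")
  obsR2Y <- r2y(fitOplsda(x, y, nOrtho = nOrtho, scaling = scaling))
  obsQ2 <- if (computeQ2) {
    q2CrossVal(x, y, nFolds = nFolds, seed = substreamSeed(seed, "cv"),
               nOrtho = nOrtho, scaling = scaling)$Q2
  } else {
    NA_real_
  }
  permR2Y <- numeric(nPerm)
  permQ2 <- numeric(nPerm)
  perms <- withSeed(substreamSeed(seed, "perm"), {
    lapply(seq_len(nPerm), function(b) sample.int(length(y)))
  })
  for (b in seq_len(nPerm)) {
    yp <- y[perms[[b]]]
    permR2Y[b] <- r2y(fitOplsda(x, yp, nOrtho = nOrtho, scaling = scaling))
    if (computeQ2) {
      permQ2[b] <- q2CrossVal(x, yp, nFolds = nFolds,
                              seed = substreamSeed(seed, sprintf("cv%d", b)),
                              nOrtho = nOrtho, scaling = scaling)$Q2
    }
  }
  list(
    pR2Y = (sum(permR2Y >= obsR2Y) + 1) / (nPerm + 1),
    pQ2 = if (computeQ2) (sum(permQ2 >= obsQ2) + 1) / (nPerm + 1) else NA_real_,
    observedR2Y = obsR2Y, observedQ2 = obsQ2, nPerm = nPerm
  )
}

#' CV-ANOVA on cross-validated predictions
#'
#' One-way ANOVA of the out-of-fold predictions grouped by class:
#' `F = (SSB / (k - 1)) / (SSW / (n - k))` with k = 2 classes, p from the
#' F distribution with (1, n - 2) degrees of freedom, and
#' `Eta2 = SSB / SST` as effect size. A model that truly separates the
#' classes concentrates the cross-validated predictions around the coded
#' class means, giving a large F.
#'
#' @param predictions out-of-fold predictions, one per sample (from
#'   [q2CrossVal()]).
#' @param y class labels aligned with `predictions`.
#' @return list with `F`, `p`, `eta2`, `df`. Zero within-class residual
#'   yields `F = Inf`, `p = 0` with a warning.
#' @examples
#' cvAnova(c(0.9, 1.1, 1.0, -0.9, -1.1, -1.0), rep(c("A", "C"), each = 3))
#' @export
cvAnova <- function(predictions, y) {
  y <- as.character(y)
  if (length(predictions) != length(y)) {
    stop("cross-validated predictions are required for every sample")
  }
  n <- length(y)
  lev <- sort(unique(y))
  k <- length(lev)
  if (k < 2L) stop("at least two classes are required")
  grand <- mean(predictions)
  ssb <- sum(vapply(lev, function(l) {
    i <- y == l
    sum(i) * (mean(predictions[i]) - grand)^2
  }, numeric(1)))
  ssw <- sum(vapply(lev, function(l) {
    i <- y == l
    sum((predictions[i] - mean(predictions[i]))^2)
  }, numeric(1)))
  sst <- ssb + ssw
  eta2 <- if (sst > 0) ssb / sst else NA_real_
  if (ssw <= 0) {
    warning("zero within-class residual; F reported as Inf with p = 0")
    return(list(F = Inf, p = 0, eta2 = eta2, df = c(k - 1L, n - k)))
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       eta2 = eta2, df = c(k - 1L, n - k))
}

#' Choose the number of orthogonal components automatically
#'
#' Starting from zero orthogonal components, adds one at a time while the
#' cross-validated Q2 improves by at least `minGain` (default 0.01, a
#' common stopping heuristic).
#'
#' @inheritParams q2CrossVal
#' @param maxOrtho largest number of orthogonal components to consider.
#' @param minGain minimum Q2 improvement to keep adding components.
#' @return list with the chosen `nOrtho` and the `Q2` path per candidate.
#' @export
chooseNOrtho <- function(x, y, maxOrtho = 3L, minGain = 0.01,
                         nFolds = 10L, seed = 1L,
                         scaling = c("uv", "center", "pareto", "none")) {
  scaling <- match.arg(scaling)
  q2path <- numeric(0)
  best <- 0L
  for (k in 0:maxOrtho) {
    q <- q2CrossVal(x, y, nFolds = nFolds, seed = seed, nOrtho = k,
                    scaling = scaling)$Q2
    q2path <- c(q2path, q)
    if (k > 0 && q - q2path[k] < minGain) break
    best <- k
  }
  list(nOrtho = best, Q2 = q2path)
}

#' Full validation of an O-PLS-DA discrimination
#'
#' Convenience wrapper running [q2CrossVal()], [permutationTest()] and
#' [cvAnova()] and returning an [OplsdaValidation-class].
#'
#' @inheritParams permutationTest
#' @return an [OplsdaValidation-class].
#' @export
validateOplsda <- function(x, y, nFolds = 10L, nPerm = 1000L, seed = 1L,
                           nOrtho = 1L,
                           scaling = c("uv", "center", "pareto", "none")) {
  scaling <- match.arg(scaling)
  cv <- q2CrossVal(x, y, nFolds = nFolds, seed = substreamSeed(seed, "cv"),
                   nOrtho = nOrtho, scaling = scaling)
  pt <- permutationTest(x, y, nPerm = nPerm, seed = seed, nOrtho = nOrtho,
                        nFolds = nFolds, scaling = scaling, computeQ2 = TRUE)
  an <- cvAnova(cv$predictions, y)
  methods::new("OplsdaValidation",
               Q2 = cv$Q2, permPR2Y = pt$pR2Y, permPQ2 = pt$pQ2,
               nPerm = as.integer(nPerm), cvF = an$F, cvP = an$p,
               cvEta2 = an$eta2, nFolds = as.integer(nFolds),
               seed = as.integer(seed))
}
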