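#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor sd var dist hclust prcomp pf pt p.adjust quantile
#'   setNames rnorm runif rbinom aggregate
#' @importFrom utils read.delim write.table head
NULL

#' MetabolomeExperiment: a samples x metabolites peak-height table
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' `"peaks"` assay with metabolites as rows and samples as columns, plus
#' per-sample metadata (`bird_id`, `day`, `period`, `body_mass_g`,
#' `liver_mass_g`). The `normalized` flag in `metadata()` records whether
#' total-ion-current normalization has been applied.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("MetabolomeExperiment", contains = "SummarizedExperiment")

setValidity("MetabolomeExperiment", function(object) {
  msg <- character(0)
  a <- SummarizedExperiment::assay(object)
  if (anyDuplicated(rownames(a))) msg <- c(msg, "duplicate metabolite names")
  if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicate sample names")
  if (any(!is.finite(a))) msg <- c(msg, "non-finite peak heights")
  if (any(a < 0)) msg <- c(msg, "negative peak heights")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("day", "period")) {
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("missing colData field '%s'", f))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolomeExperiment
#'
#' @param values numeric samples x metabolites matrix (rows = samples) of
#'   non-negative peak heights; row names are sample ids, column names
#'   metabolite names.
#' @param sampleData data.frame of per-sample metadata with at least a `day`
#'   column; a `period` column is derived with [assignPeriod()] when absent.
#' @param normalized logical; has TIC normalization already been applied?
#' @param strictPeriods passed to [assignPeriod()] when deriving periods.
#' @return a [MetabolomeExperiment-class] object.
#' @examples
#' m <- matrix(abs(rnorm(12)), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("met", 1:4)))
#' me <- MetabolomeExperiment(m, data.frame(day = c(4, 10, 16)))
#' periodLabels(me)
#' @export
MetabolomeExperiment <- function(values, sampleData,
                                 normalized = FALSE, strictPeriods = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("sample_%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("metabolite names (column names of 'values') are required")
  }
  sampleData <- as.data.frame(sampleData)
  if (nrow(sampleData) != nrow(values)) {
    stop("one metadata row per sample is required")
  }
  if (!"day" %in% colnames(sampleData)) stop("sampleData needs a 'day' column")
  if (!"period" %in% colnames(sampleData)) {
    sampleData$period <- vapply(sampleData$day, assignPeriod, character(1),
                                strict = strictPeriods)
  }
  rownames(sampleData) <- rownames(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(peaks = t(values)),
    colData = S4Vectors::DataFrame(sampleData)
  )
  S4Vectors::metadata(se)$normalized <- isTRUE(normalized)
  methods::new("MetabolomeExperiment", se)
}

#' Orthogonal PLS discriminant analysis model
#'
#' One predictive component plus `nOrtho` orthogonal (y-uncorrelated)
#' components fitted by the O-PLS algorithm. Class labels are coded through
#' `coding` (a named +1/-1 vector); x-scaling parameters are stored so the
#' model can score held-out samples.
#'
#' @slot weights predictive weight vector w (unit norm).
#' @slot scores predictive score vector t.
#' @slot loadings predictive loading vector p.
#' @slot yLoading scalar y-loading c.
#' @slot orthoWeights,orthoScores,orthoLoadings orthogonal component matrices.
#' @slot R2Y fraction of coded-label variance explained in-sample.
#' @slot RMSEE root mean square error of estimation.
#' @slot coding named numeric (+1/-1) class coding.
#' @slot xCenter,xScale,yCenter training centering/scaling parameters.
#' @slot fitted in-sample predictions on the coded-y scale.
#' @slot nOrtho number of orthogonal components.
#' @slot featureNames metabolite names.
#' @export
setClass("OplsdaModel", representation(
  weights = "numeric", scores = "numeric", loadings = "numeric",
  yLoading = "numeric",
  orthoWeights = "matrix", orthoScores = "matrix", orthoLoadings = "matrix",
  R2Y = "numeric", RMSEE = "numeric", coding = "numeric",
  xCenter = "numeric", xScale = "numeric", yCenter = "numeric",
  fitted = "numeric", nOrtho = "integer", featureNames = "character"
))

setValidity("OplsdaModel", function(object) {
  msg <- character(0)
  if (object@R2Y < -1e-8 || object@R2Y > 1 + 1e-8) msg <- c(msg, "R2Y outside [0,1]")
  if (object@RMSEE < 0) msg <- c(msg, "negative RMSEE")
  if (object@nOrtho > 0) {
    dots <- abs(crossprod(object@orthoScores, object@scores))
    lim <- 1e-6 * sqrt(colSums(object@orthoScores^2)) * sqrt(sum(object@scores^2))
    if (any(dots > pmax(lim, 1e-12))) {
      msg <- c(msg, "predictive scores not orthogonal to orthogonal scores")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Validation report for an O-PLS-DA model
#'
#' Holds cross-validated Q2, permutation p-values for R2Y and Q2, and the
#' CV-ANOVA F test on the cross-validated predictions.
#'
#' @slot Q2 cross-validated predictive fraction (<= 1, may be negative).
#' @slot permPR2Y,permPQ2 permutation p-values ((b+1)/(n+1) convention).
#' @slot nPerm number of permutations.
#' @slot cvF,cvP,cvEta2 CV-ANOVA F statistic, p-value and effect size.
#' @slot nFolds folds used for cross-validation.
#' @slot seed seed governing folds and permutations.
#' @export
setClass("OplsdaValidation", representation(
  Q2 = "numeric", permPR2Y = "numeric", permPQ2 = "numeric",
  nPerm = "integer", cvF = "numeric", cvP = "numeric", cvEta2 = "numeric",
  nFolds = "integer", seed = "integer"
))

setValidity("OplsdaValidation", function(object) {
  msg <- character(0)
  if (length(object@Q2) && object@Q2 > 1 + 1e-8) msg <- c(msg, "Q2 > 1")
  for (p in c(object@permPR2Y, object@permPQ2)) {
    if (!is.na(p) && (p <= 0 || p > 1)) msg <- c(msg, "permutation p outside (0,1]")
  }
  if (length(object@cvEta2) && !is.na(object@cvEta2) &&
      (object@cvEta2 < 0 || object@cvEta2 > 1)) msg <- c(msg, "eta2 outside [0,1]")
  if (length(object@cvF) && !is.na(object@cvF) && object@cvF < 0) {
    msg <- c(msg, "negative F")
  }
  if (length(msg)) msg else TRUE
})

#' Principal component analysis result
#'
#' @slot scores samples x k score matrix.
#' @slot loadings metabolites x k orthonormal loading matrix; each column is
#'   sign-fixed so its largest-magnitude entry is positive.
#' @slot varianceExplained fraction of total variance per component.
#' @export
setClass("PcaResult", representation(
  scores = "matrix", loadings = "matrix", varianceExplained = "numeric"
))

setValidity("PcaResult", function(object) {
  msg <- character(0)
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(g)))) > 1e-8) msg <- c(msg, "loadings not orthonormal")
  ve <- object@varianceExplained
  if (any(ve < -1e-12 | ve > 1 + 1e-12)) msg <- c(msg, "variance fractions outside [0,1]")
  if (is.unsorted(rev(ve))) msg <- c(msg, "variance fractions not non-increasing")
  if (sum(ve) > 1 + 1e-8) msg <- c(msg, "variance fractions sum > 1")
  if (length(msg)) msg else TRUE
})

#' A per-period (or core) metabolite correlation network
#'
#' Nodes are metabolites; edges carry the correlation coefficient `r`, its
#' p-value, the within-period BH FDR and the correlation sign. Edge endpoints
#' are stored with `from < to` lexicographically so edge identity is
#' canonical.
#'
#' @slot period period label ("A", "B", "C", "core", ...).
#' @slot nodes character vector of metabolite names (may include isolated
#'   nodes, e.g. in first-neighbor subnetworks).
#' @slot edges data.frame with columns from, to, r, p, fdr, sign.
#' @export
setClass("PeriodNetwork", representation(
  period = "character", nodes = "character", edges = "data.frame"
))

setValidity("PeriodNetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  need <- c("from", "to", "r", "p", "fdr", "sign")
  if (!all(need %in% colnames(e))) {
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loop edge present")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be stored with from < to")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r"))) {
      msg <- c(msg, "duplicate edges")
    }
    if (!all(c(e$from, e$to) %in% object@nodes)) {
      msg <- c(msg, "edge endpoint missing from node set")
    }
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  if (length(msg)) msg else TRUE
})

#' @noRd
newPeriodNetwork <- function(period, nodes, edges) {
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    if (any(swap)) {
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  methods::new("PeriodNetwork", period = period,
               nodes = sort(unique(nodes)), edges = edges)
}

#' @noRd
emptyEdgeFrame <- function() {
  data.frame(from = character(0), to = character(0), r = numeric(0),
             p = numeric(0), fdr = numeric(0), sign = character(0),
             stringsAsFactors = FALSE)
}
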