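# Generics, accessors and show methods for the S4 surface.

#' Extract the samples x metabolites matrix
#'
#' @param object a [MetabolomeExperiment-class].
#' @return numeric matrix with samples as rows (the orientation all
#'   statistical functions in this package use).
#' @export
setGeneric("metaboliteMatrix", function(object) standardGeneric("metaboliteMatrix"))

#' @rdname metaboliteMatrix
#' @export
setMethod("metaboliteMatrix", "MetabolomeExperiment", function(object) {
  t(SummarizedExperiment::assay(object, "peaks"))
})

#' Per-sample period labels
#' @param object a [MetabolomeExperiment-class].
#' @return character vector of period labels, one per sample.
#' @export
setGeneric("periodLabels", function(object) standardGeneric("periodLabels"))

#' @rdname periodLabels
#' @export
setMethod("periodLabels", "MetabolomeExperiment", function(object) {
  as.character(SummarizedExperiment::colData(object)$period)
})

#' Per-sample days post-hatch
#' @param object a [MetabolomeExperiment-class].
#' @return integer vector of days, one per sample.
#' @export
setGeneric("sampleDays", function(object) standardGeneric("sampleDays"))

#' @rdname sampleDays
#' @export
setMethod("sampleDays", "MetabolomeExperiment", function(object) {
  as.integer(SummarizedExperiment::colData(object)$day)
})

#' Has total-ion-current normalization been applied?
#' @param object a [MetabolomeExperiment-class].
#' @return logical flag.
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "MetabolomeExperiment", function(object) {
  isTRUE(S4Vectors::metadata(object)$normalized)
})

setMethod("show", "MetabolomeExperiment", function(object) {
  cat(sprintf("MetabolomeExperiment: %d metabolites x %d samples\n",
              nrow(object), ncol(object)))
  days <- sampleDays(object)
  cat(sprintf("  days %s; periods %s; TIC-normalized: %s\n",
              paste(range(days), collapse = "-"),
              paste(sort(unique(periodLabels(object))), collapse = "/"),
              isNormalized(object)))
})

#' Model accessors
#'
#' `r2y()`, `rmsee()` and `q2()` return the named model quality statistics;
#' `predictiveScores()` and `orthogonalScores()` return score vectors/matrices.
#'
#' @param object an [OplsdaModel-class] or [OplsdaValidation-class].
#' @return numeric scalar, vector or matrix as described.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("r2y", function(object) standardGeneric("r2y"))
#' @rdname model-accessors
#' @export
setMethod("r2y", "OplsdaModel", function(object) object@R2Y)

#' @rdname model-accessors
#' @export
setGeneric("rmsee", function(object) standardGeneric("rmsee"))
#' @rdname model-accessors
#' @export
setMethod("rmsee", "OplsdaModel", function(object) object@RMSEE)

#' @rdname model-accessors
#' @export
setGeneric("q2", function(object) standardGeneric("q2"))
#' @rdname model-accessors
#' @export
setMethod("q2", "OplsdaValidation", function(object) object@Q2)

#' @rdname model-accessors
#' @export
setGeneric("predictiveScores", function(object) standardGeneric("predictiveScores"))
#' @rdname model-accessors
#' @export
setMethod("predictiveScores", "OplsdaModel", function(object) object@scores)

#' @rdname model-accessors
#' @export
setGeneric("orthogonalScores", function(object) standardGeneric("orthogonalScores"))
#' @rdname model-accessors
#' @export
setMethod("orthogonalScores", "OplsdaModel", function(object) object@orthoScores)

setMethod("show", "OplsdaModel", function(object) {
  cat(sprintf("OplsdaModel: 1 predictive + %d orthogonal component(s), %d metabolites\n",
              object@nOrtho, length(object@weights)))
  cat(sprintf("  classes %s; R2Y = %.3f; RMSEE = %.3f\n",
              paste(sprintf("%s(%+d)", names(object@coding), object@coding),
                    collapse = " vs "),
              object@R2Y, object@RMSEE))
})

setMethod("show", "OplsdaValidation", function(object) {
  cat("OplsdaValidation:\n")
  cat(sprintf("  Q2 (%d folds) = %.3f\n", object@nFolds, object@Q2))
  cat(sprintf("  permutation (%dX): pR2Y = %.4g, pQ2 = %.4g\n",
              object@nPerm, object@permPR2Y, object@permPQ2))
  cat(sprintf("  CV-ANOVA: F = %.1f, p = %.3g, Eta2 = %.2f\n",
              object@cvF, object@cvP, object@cvEta2))
})

setMethod("show", "PcaResult", function(object) {
  cat(sprintf("PcaResult: %d component(s) over %d samples x %d metabolites\n",
              ncol(object@scores), nrow(object@scores), nrow(object@loadings)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * object@varianceExplained),
                    collapse = ", ")))
})

#' Network accessors
#'
#' @param object a [PeriodNetwork-class].
#' @return `networkNodes()` the node name vector, `networkEdges()` the edge
#'   data.frame, `networkPeriod()` the period label.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname network-accessors
#' @export
setMethod("networkNodes", "PeriodNetwork", function(object) object@nodes)

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname network-accessors
#' @export
setMethod("networkEdges", "PeriodNetwork", function(object) object@edges)

#' @rdname network-accessors
#' @export
setGeneric("networkPeriod", function(object) standardGeneric("networkPeriod"))
#' @rdname network-accessors
#' @export
setMethod("networkPeriod", "PeriodNetwork", function(object) object@period)

setMethod("show", "PeriodNetwork", function(object) {
  cat(sprintf("PeriodNetwork [%s]: %d nodes, %d edges\n",
              object@period, length(object@nodes), nrow(object@edges)))
})
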