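# Preprocessing: total-ion-current normalization, Z-scores, composite
# group trajectories and hierarchical clustering.

#' Normalize peak heights to the mean total ion current
#'
#' Each sample is scaled by (cohort mean total signal) / (its own total
#' signal), so after normalization every sample's total equals the cohort
#' mean total. Idempotent: applying it twice equals applying once.
#'
#' @param object a [MetabolomeExperiment-class] with non-negative values and
#'   at least one positive value per sample.
#' @return the normalized [MetabolomeExperiment-class] (`isNormalized()`
#'   becomes TRUE); metabolite order and metadata are preserved.
#' @export
normalizeTIC <- function(object) {
  stopifnot(methods::is(object, "MetabolomeExperiment"))
  a <- SummarizedExperiment::assay(object, "peaks")
  totals <- colSums(a)
  if (any(totals <= 0)) {
    bad <- colnames(a)[totals <= 0]
    stop(sprintf("sample(s) with zero total signal: %s",
                 paste(bad, collapse = ", ")))
  }
  target <- mean(totals)
  SummarizedExperiment::assay(object, "peaks") <-
    sweep(a, 2, target / totals, `*`)
  S4Vectors::metadata(object)$normalized <- TRUE
  methods::validObject(object)
  object
}

#' Per-metabolite Z-scores across all samples
#'
#' Standardizes every metabolite to mean 0 and sample SD 1 (n - 1
#' denominator) across all samples jointly — not within period, so that
#' composite trajectories across days share one scale. Constant metabolites
#' map to all zeros with a warning.
#'
#' @param object a [MetabolomeExperiment-class] or a samples x metabolites
#'   numeric matrix with >= 2 samples.
#' @return samples x metabolites matrix of Z-scores.
#' @examples
#' zScores(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "m"))) # -1, 0, 1
#' @export
zScores <- function(object) {
  x <- if (methods::is(object, "MetabolomeExperiment")) {
    metaboliteMatrix(object)
  } else {
    as.matrix(object)
  }
  if (nrow(x) < 2L) stop("at least two samples are needed to standardize")
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  const <- s < .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  if (any(const)) {
    warning(sprintf("constant metabolite(s) set to zero Z-scores: %s",
                    paste(colnames(x)[const], collapse = ", ")))
    s[const] <- 1
  }
  z <- sweep(sweep(x, 2, mu, `-`), 2, s, `/`)
  z[, const] <- 0
  z
}

#' Composite Z-score trajectories for metabolite groups
#'
#' For each named group and each day, the mean Z-score of the group's
#' members over that day's samples — the summary used to visualize how
#' opposing early/late metabolite signatures cross over during the
#' nutrient-source transition.
#'
#' @param z samples x metabolites Z-score matrix (see [zScores()]).
#' @param groups named list of metabolite name vectors.
#' @param days integer vector of day post-hatch, one per sample.
#' @return data.frame with columns `group`, `day`, `mean_z`, `n`.
#' @export
compositeZScore <- function(z, groups, days) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  if (length(days) != nrow(z)) stop("'days' must align with the samples")
  missing <- setdiff(unlist(groups), colnames(z))
  if (length(missing)) {
    stop(sprintf("unknown metabolite name(s): %s", paste(missing, collapse = ", ")))
  }
  dayLevels <- sort(unique(days))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    member <- z[, groups[[g]], drop = FALSE]
    perSample <- rowMeans(member)
    data.frame(
      group = g, day = dayLevels,
      mean_z = vapply(dayLevels, function(d) mean(perSample[days == d]), numeric(1)),
      n = vapply(dayLevels, function(d) sum(days == d), integer(1)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of samples or metabolites
#'
#' Deterministic agglomerative clustering of the Z-score matrix along the
#' chosen axis (ties broken by input order, as in [stats::hclust()]). With
#' a metabolite-to-pathway map, metabolite rows are aggregated to pathway
#' means before clustering, mirroring pathway-level heat maps.
#'
#' @param z samples x metabolites Z-score matrix.
#' @param axis "samples" or "metabolites".
#' @param linkage agglomeration method understood by [stats::hclust()]
#'   (default "average").
#' @param distance distance metric understood by [stats::dist()]
#'   (default "euclidean").
#' @param pathwayMap optional data.frame with columns `metabolite`,
#'   `pathway` (only used for `axis = "metabolites"`).
#' @return list with the `hclust` object (`tree`), the leaf `order` and the
#'   leaf `labels` (for heat-map rendering).
#' @export
hclusterMetabolome <- function(z, axis = c("samples", "metabolites"),
                               linkage = "average", distance = "euclidean",
                               pathwayMap = NULL) {
  axis <- match.arg(axis)
  okLinkage <- c("ward.D", "ward.D2", "single", "complete", "average",
                 "mcquitty", "median", "centroid")
  okDistance <- c("euclidean", "maximum", "manhattan", "canberra",
                  "binary", "minkowski")
  if (!linkage %in% okLinkage) stop(sprintf("unknown linkage '%s'", linkage))
  if (!distance %in% okDistance) stop(sprintf("unknown distance '%s'", distance))
  items <- if (axis == "samples") z else t(z)
  if (axis == "metabolites" && !is.null(pathwayMap)) {
    stopifnot(all(c("metabolite", "pathway") %in% colnames(pathwayMap)))
    keep <- pathwayMap$metabolite %in% rownames(items)
    pm <- pathwayMap[keep, , drop = FALSE]
    agg <- rowsum(items[pm$metabolite, , drop = FALSE], group = pm$pathway)
    items <- agg / as.vector(table(pm$pathway)[rownames(agg)])
  }
  if (nrow(items) < 2L) stop("need at least two items on the clustering axis")
  tree <- stats::hclust(stats::dist(items, method = distance), method = linkage)
  list(tree = tree, order = tree$order, labels = rownames(items)[tree$order])
}
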