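# Correlation-network analysis: per-period networks, the core
# intersection, first-neighbor expansion, topology metrics and
# growth-phenotype associations.

#' Pairwise metabolite correlations within a period
#'
#' Correlation matrix with p-values from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (for
#' Spearman this is the usual large-sample approximation). Metabolites
#' constant within the period yield NA correlations, recorded as missing.
#'
#' @param x samples x metabolites matrix restricted to one period
#'   (>= 4 samples).
#' @param method "pearson" (default) or "spearman".
#' @return list with symmetric matrices `r` and `p`, the sample size `n`
#'   and the `method`.
#' @export
pairwiseCorrelations <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("at least 4 samples are required within a period")
  r <- suppressWarnings(stats::cor(x, method = method))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(r) <- 1
  diag(p) <- 0
  list(r = r, p = p, n = n, method = method)
}

#' Build a period correlation network
#'
#' BH-FDR is applied over all metabolite pairs tested within the period;
#' an edge joins metabolites i and j iff `|r_ij| > rThreshold` and
#' `fdr_ij < fdrCutoff`. The absolute value is thresholded (not signed r)
#' so strong negative correlations are kept, with the sign retained as an
#' edge attribute. Metabolites with no qualifying edge are excluded —
#' networks are defined by their edges.
#'
#' @param correlations output of [pairwiseCorrelations()].
#' @param rThreshold correlation magnitude threshold (default 0.85).
#' @param fdrCutoff FDR cutoff (default 0.05).
#' @param period label for the network ("A", "B", "C", ...).
#' @return a [PeriodNetwork-class] (possibly empty).
#' @export
buildPeriodNetwork <- function(correlations, rThreshold = 0.85,
                               fdrCutoff = 0.05, period = "A") {
  assertScalarNumber(rThreshold, "rThreshold", lower = 0, upper = 1)
  assertScalarNumber(fdrCutoff, "fdrCutoff", lower = 0, upper = 1)
  r <- correlations$r
  p <- correlations$p
  mets <- colnames(r)
  if (is.null(mets) || length(mets) < 2L) {
    return(newPeriodNetwork(period, character(0), emptyEdgeFrame()))
  }
  ut <- upper.tri(r)
  idx <- which(ut & !is.na(r), arr.ind = TRUE)
  if (!nrow(idx)) return(newPeriodNetwork(period, character(0), emptyEdgeFrame()))
  rv <- r[idx]
  pv <- p[idx]
  fdr <- bhFDR(pv)
  keep <- abs(rv) > rThreshold & fdr < fdrCutoff
  if (!any(keep)) return(newPeriodNetwork(period, character(0), emptyEdgeFrame()))
  edges <- data.frame(
    from = mets[idx[keep, 1]], to = mets[idx[keep, 2]],
    r = rv[keep], p = pv[keep], fdr = fdr[keep],
    sign = ifelse(rv[keep] >= 0, "pos", "neg"),
    stringsAsFactors = FALSE
  )
  newPeriodNetwork(period, unique(c(edges$from, edges$to)), edges)
}

#' @noRd
edgeKeys <- function(net) {
  e <- networkEdges(net)
  paste(e$from, e$to, sep = "\r")
}

#' Core network: correlations maintained across all three periods
#'
#' `mode = "edge"` (default): edges present (same unordered metabolite
#' pair, any sign) in all three period networks; the core is then a
#' subgraph of each period network. Core edge attributes summarise the
#' three periods: `r` is the mean of the period correlations, `fdr` the
#' maximum (most conservative), `p` the maximum, and `sign` follows the
#' mean r. `mode = "node"`: nodes carrying at least one qualifying edge in
#' every period; edges are the all-period intersection edges among them.
#'
#' @param netA,netB,netC [PeriodNetwork-class] objects over a shared
#'   metabolite universe.
#' @param mode "edge" or "node".
#' @return a [PeriodNetwork-class] with period `"core"`.
#' @export
coreNetwork <- function(netA, netB, netC, mode = c("edge", "node")) {
  mode <- match.arg(mode)
  nets <- list(netA, netB, netC)
  keys <- lapply(nets, edgeKeys)
  common <- Reduce(intersect, keys)
  if (length(common)) {
    rows <- lapply(nets, function(nt) {
      e <- networkEdges(nt)
      e[match(common, edgeKeys(nt)), , drop = FALSE]
    })
    rmean <- rowMeans(cbind(rows[[1]]$r, rows[[2]]$r, rows[[3]]$r))
    edges <- data.frame(
      from = rows[[1]]$from, to = rows[[1]]$to,
      r = rmean,
      p = pmax(rows[[1]]$p, rows[[2]]$p, rows[[3]]$p),
      fdr = pmax(rows[[1]]$fdr, rows[[2]]$fdr, rows[[3]]$fdr),
      sign = ifelse(rmean >= 0, "pos", "neg"),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- emptyEdgeFrame()
  }
  if (mode == "edge") {
    nodes <- unique(c(edges$from, edges$to))
  } else {
    nodes <- Reduce(intersect, lapply(nets, networkNodes))
    edges <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
  }
  newPeriodNetwork("core", nodes, edges)
}

#' First neighbors of the core within one period
#'
#' Subnetwork of `periodNet` induced by the core nodes plus every node
#' adjacent to a core node in that period. Core nodes isolated in the
#' period contribute only themselves.
#'
#' @param core the core [PeriodNetwork-class].
#' @param periodNet one period's [PeriodNetwork-class].
#' @return a [PeriodNetwork-class] labelled
#'   `"<period>_first_neighbors"`.
#' @export
firstNeighbors <- function(core, periodNet) {
  coreNodes <- networkNodes(core)
  e <- networkEdges(periodNet)
  adjacent <- unique(c(e$to[e$from %in% coreNodes], e$from[e$to %in% coreNodes]))
  nodes <- unique(c(coreNodes, adjacent))
  keep <- e$from %in% nodes & e$to %in% nodes
  newPeriodNetwork(paste0(networkPeriod(periodNet), "_first_neighbors"),
                   nodes, e[keep, , drop = FALSE])
}

#' Topology metrics of a network
#'
#' The ten descriptive statistics used to compare period networks.
#' Conventions: the clustering coefficient is the mean local clustering
#' over all nodes with degree < 2 contributing 0; the characteristic path
#' length is the mean shortest-path length over all connected node pairs
#' (NA when no pair is connected); diameter and radius are the max/min
#' eccentricity within the largest connected component; heterogeneity is
#' the population SD of the degree sequence over its mean (0 when the mean
#' degree is 0); centralization is `(N/(N-2)) * (maxdeg/(N-1) - density)`
#' for N >= 3 and 0 otherwise.
#'
#' @param net a nonempty [PeriodNetwork-class].
#' @return one-row data.frame with columns `n_nodes`, `n_edges`,
#'   `avg_neighbors`, `diameter`, `radius`, `char_path_length`,
#'   `clustering_coefficient`, `density`, `heterogeneity`,
#'   `centralization`, `n_components`.
#' @export
topologyMetrics <- function(net) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  if (n == 0L) stop("topology metrics are undefined for an empty graph")
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  nE <- nrow(e)
  deg <- igraph::degree(g)
  density <- if (n >= 2) 2 * nE / (n * (n - 1)) else 0
  localCC <- igraph::transitivity(g, type = "local", isolates = "zero")
  localCC[deg < 2] <- 0
  comps <- igraph::components(g)
  largest <- which(comps$membership == which.max(comps$csize))
  sub <- igraph::induced_subgraph(g, largest)
  dSub <- igraph::distances(sub)
  ecc <- apply(dSub, 1, max)
  dAll <- igraph::distances(g)
  finitePairs <- dAll[upper.tri(dAll)]
  finitePairs <- finitePairs[is.finite(finitePairs)]
  cpl <- if (length(finitePairs)) mean(finitePairs) else NA_real_
  meanDeg <- mean(deg)
  het <- if (meanDeg > 0) sqrt(mean(deg^2) - meanDeg^2) / meanDeg else 0
  central <- if (n >= 3) (n / (n - 2)) * (max(deg) / (n - 1) - density) else 0
  data.frame(
    n_nodes = n, n_edges = nE, avg_neighbors = 2 * nE / n,
    diameter = max(ecc), radius = min(ecc), char_path_length = cpl,
    clustering_coefficient = mean(localCC), density = density,
    heterogeneity = het, centralization = central,
    n_components = comps$no
  )
}

#' Correlate metabolites with a growth phenotype
#'
#' Per-metabolite correlation with a phenotype (allometric ratio or total
#' liver mass) pooled across all days, p from the t-transform, BH-FDR over
#' metabolites; the significant set is `fdr < 0.05` partitioned by sign.
#'
#' @param x samples x metabolites matrix (>= 4 samples).
#' @param phenotype numeric phenotype aligned to samples (non-constant).
#' @param phenotypeName label recorded in the output (e.g.
#'   "allometric_ratio").
#' @param method correlation method as in [pairwiseCorrelations()].
#' @return data.frame with columns `metabolite`, `phenotype`, `r`, `p`,
#'   `fdr`, `direction`.
#' @export
growthAssociation <- function(x, phenotype, phenotypeName = "phenotype",
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("at least 4 samples are required")
  if (length(phenotype) != n) stop("phenotype must align with samples")
  if (stats::sd(phenotype) == 0) stop("phenotype is constant")
  r <- suppressWarnings(drop(stats::cor(x, phenotype, method = method)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  data.frame(
    metabolite = colnames(x), phenotype = phenotypeName,
    r = unname(r), p = unname(p), fdr = unname(bhFDR(p)),
    direction = unname(ifelse(is.na(r), NA, ifelse(r >= 0, "positive", "negative"))),
    stringsAsFactors = FALSE
  )
}

#' Built-in xenometabolite lookup
#'
#' Compounds of likely non-endogenous origin detected in post-hatch liver,
#' with their putative sources (feed components, environmental
#' contaminants, plastics).
#'
#' @return data.frame with columns `name`, `source`.
#' @export
xenoLookup <- function() {
  data.frame(
    name = c("1,2,4-benzenetriol", "benzoic acid", "pyrogallol",
             "methanolphosphate", "nornicotine", "2-piperidinobenzonitrile",
             "levoglucosan", "maleimide", "terephthalic acid",
             "2,5-dihydroxypyrazine", "1,3,5-trimethylcyanuric",
             "conduritol-beta-epoxide"),
    source = c("corn-derived feed component", "corn-derived feed component",
               "corn-derived feed component",
               "possible fungal contaminant of feed grain",
               "environmental nicotine metabolite",
               "pesticide/herbicide synthesis intermediate",
               "cellulose pyrolysis product (biochar feed additive)",
               "plastic synthesis compound (possible microplastic)",
               "plastic synthesis compound (possible microplastic)",
               "uncertain origin", "uncertain origin", "uncertain origin"),
    stringsAsFactors = FALSE
  )
}

#' Flag xenometabolites by name
#'
#' Case-insensitive exact-name matching against a lookup of known
#' non-endogenous compounds; unmatched names are left unflagged.
#'
#' @param names character vector of metabolite names.
#' @param lookup data.frame with columns `name`, `source` (default
#'   [xenoLookup()]).
#' @return data.frame with columns `name`, `is_xeno`, `source`.
#' @examples
#' annotateXenometabolites(c("nornicotine", "glucose", "MALEIMIDE"))
#' @export
annotateXenometabolites <- function(names, lookup = xenoLookup()) {
  idx <- match(tolower(names), tolower(lookup$name))
  data.frame(
    name = names,
    is_xeno = !is.na(idx),
    source = ifelse(is.na(idx), NA_character_, lookup$source[idx]),
    stringsAsFactors = FALSE
  )
}
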