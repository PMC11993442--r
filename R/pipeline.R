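# End-to-end orchestration: simulate/load -> morphometrics -> preprocessing
# -> PCA/O-PLS-DA/differential -> networks -> report bundle on disk.

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with the defaults used throughout:
#' edge threshold |r| > 0.85 at FDR < 0.05, VIP > 1 for the differential
#' table, one orthogonal component, 10-fold cross-validation and 1000
#' permutations.
#'
#' @param synthetic run on a generated study (TRUE) or on `inputDir`.
#' @param syntheticConfig a [syntheticConfig()] (synthetic mode).
#' @param inputDir directory with `samples.tsv` and `matrix.tsv`
#'   (non-synthetic mode).
#' @param outdir output directory for the report bundle.
#' @param rThreshold,fdrCutoff,vipCutoff statistical cutoffs.
#' @param nOrtho,nFolds,nPerm,scaling O-PLS-DA settings.
#' @param corMethod correlation method for networks and growth association.
#' @param linkage,distance hierarchical clustering settings.
#' @param groups named list of metabolite groups for composite Z-score
#'   trajectories; NULL uses the synthetic config's group1/group2 when
#'   available.
#' @param log2BeforeZscore log2(x + 1)-transform normalized intensities
#'   before Z-scoring and latent-variable modeling (default FALSE,
#'   matching analyses that model peak heights directly; TRUE fits
#'   O-PLS-DA and friends on the log scale, which better matches the
#'   approximately log-normal distribution of peak heights — fold changes
#'   always remain on raw normalized means).
#' @param nTrees random-forest size.
#' @param seed master seed; every stochastic stage draws from a named
#'   substream of it.
#' @return validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(synthetic = TRUE,
                           syntheticConfig = allomet::syntheticConfig(),
                           inputDir = NULL,
                           outdir = tempfile("allomet_run_"),
                           rThreshold = 0.85, fdrCutoff = 0.05, vipCutoff = 1,
                           nOrtho = 1L, nFolds = 10L, nPerm = 1000L,
                           scaling = "uv",
                           corMethod = "pearson",
                           linkage = "average", distance = "euclidean",
                           groups = NULL,
                           log2BeforeZscore = FALSE,
                           nTrees = 500L,
                           seed = 1L) {
  assertScalarNumber(rThreshold, "rThreshold", lower = 0, upper = 1)
  assertScalarNumber(fdrCutoff, "fdrCutoff", lower = 0, upper = 1)
  assertScalarNumber(vipCutoff, "vipCutoff", lower = 0)
  if (nFolds < 2L) stop("'nFolds' must be >= 2")
  if (nPerm < 1L) stop("'nPerm' must be >= 1")
  if (!synthetic && is.null(inputDir)) {
    stop("non-synthetic mode requires 'inputDir'")
  }
  cfg <- list(synthetic = isTRUE(synthetic), syntheticConfig = syntheticConfig,
              inputDir = inputDir, outdir = outdir,
              rThreshold = rThreshold, fdrCutoff = fdrCutoff,
              vipCutoff = vipCutoff,
              nOrtho = as.integer(nOrtho), nFolds = as.integer(nFolds),
              nPerm = as.integer(nPerm), scaling = scaling,
              corMethod = corMethod, linkage = linkage, distance = distance,
              groups = groups, log2BeforeZscore = isTRUE(log2BeforeZscore),
              nTrees = as.integer(nTrees), seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat, human-readable key-value file; unknown keys are rejected, absent
#' keys keep their defaults. Synthetic-generator fields live under
#' `synthetic_config` (snake_case mirrors of the [syntheticConfig()]
#' arguments days, birds_per_day, n_metabolites, effect_size_d, noise_sd,
#' seed).
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  known <- c("synthetic", "input_dir", "outdir", "r_threshold", "fdr_cutoff",
             "vip_cutoff", "n_ortho", "n_folds", "n_perm", "scaling",
             "cor_method", "linkage", "distance", "log2_before_zscore",
             "n_trees", "seed", "synthetic_config")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  scArgs <- list()
  if (!is.null(y$synthetic_config)) {
    map <- c(days = "days", birds_per_day = "birdsPerDay",
             n_metabolites = "nMetabolites", effect_size_d = "effectSizeD",
             noise_sd = "noiseSd", xeno_detect_prob = "xenoDetectProb",
             growth_cv = "growthCV", seed = "seed")
    badSc <- setdiff(names(y$synthetic_config), names(map))
    if (length(badSc)) {
      stop(sprintf("unknown synthetic_config key(s): %s",
                   paste(badSc, collapse = ", ")))
    }
    scArgs <- stats::setNames(y$synthetic_config, map[names(y$synthetic_config)])
  }
  args <- list(
    synthetic = if (is.null(y$synthetic)) TRUE else y$synthetic,
    syntheticConfig = do.call(syntheticConfig, scArgs),
    inputDir = y$input_dir
  )
  opt <- c(outdir = "outdir", r_threshold = "rThreshold",
           fdr_cutoff = "fdrCutoff", vip_cutoff = "vipCutoff",
           n_ortho = "nOrtho", n_folds = "nFolds", n_perm = "nPerm",
           scaling = "scaling", cor_method = "corMethod", linkage = "linkage",
           distance = "distance", log2_before_zscore = "log2BeforeZscore",
           n_trees = "nTrees", seed = "seed")
  for (k in names(opt)) if (!is.null(y[[k]])) args[[opt[[k]]]] <- y[[k]]
  do.call(pipelineConfig, args)
}

#' @noRd
configEcho <- function(config) {
  sc <- config$syntheticConfig
  list(
    synthetic = config$synthetic,
    input_dir = config$inputDir,
    r_threshold = config$rThreshold, fdr_cutoff = config$fdrCutoff,
    vip_cutoff = config$vipCutoff, n_ortho = config$nOrtho,
    n_folds = config$nFolds, n_perm = config$nPerm, scaling = config$scaling,
    cor_method = config$corMethod, linkage = config$linkage,
    distance = config$distance,
    log2_before_zscore = config$log2BeforeZscore,
    n_trees = config$nTrees, seed = config$seed,
    synthetic_config = if (config$synthetic) list(
      days = sc$days, birds_per_day = sc$birdsPerDay,
      n_metabolites = sc$nMetabolites, effect_size_d = sc$effectSizeD,
      noise_sd = sc$noiseSd, xeno_detect_prob = sc$xenoDetectProb,
      growth_cv = sc$growthCV, seed = sc$seed
    ) else NULL
  )
}

#' Run the complete analysis pipeline
#'
#' Executes simulate/load -> morphometrics -> normalization/Z-scores ->
#' PCA -> O-PLS-DA (A vs C) with validation -> differential table ->
#' per-period networks, core, first neighbors, topology metrics ->
#' growth associations -> xenometabolite flags. Artifacts are staged in a
#' temporary directory and moved to `config$outdir` only on success, so a
#' failing stage (reported with its stage name) leaves no partial outputs.
#' All artifacts except `run.log` are byte-identical across runs with the
#' same config and seed.
#'
#' @param config a [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list of class `"ReportBundle"` with all in-memory
#'   results and the written file paths.
#' @export
runPipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- tempfile("allomet_stage_")
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)
  logLines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(fmt, ...))
    logLines <<- c(logLines, line)
    if (!quiet) message(line)
  }
  runStage <- function(name, expr) {
    note("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  study <- runStage("input", {
    if (config$synthetic) {
      s <- generateStudy(config$syntheticConfig)
      writeStudy(s, stage)
      s
    } else {
      readStudy(config$inputDir)
    }
  })
  birds <- study$birds
  me <- study$experiment

  gs <- runStage("morphometrics", growthSummary(birds))
  phase <- allometricPhase(gs)
  writeTsv(gs, file.path(stage, "growth_summary.tsv"))
  writeTsv(data.frame(interval = names(phase), sign = unname(phase),
                      stringsAsFactors = FALSE),
           file.path(stage, "growth_phase.tsv"))

  prep <- runStage("preprocessing", {
    norm <- normalizeTIC(me)
    xNorm <- metaboliteMatrix(norm)
    z <- zScores(if (config$log2BeforeZscore) log2(xNorm + 1) else xNorm)
    groups <- config$groups
    if (is.null(groups) && config$synthetic) {
      groups <- list(group1 = config$syntheticConfig$group1,
                     group2 = config$syntheticConfig$group2)
    }
    comp <- if (!is.null(groups)) {
      compositeZScore(z, groups, sampleDays(norm))
    } else {
      NULL
    }
    clus <- hclusterMetabolome(z, axis = "samples", linkage = config$linkage,
                               distance = config$distance)
    list(norm = norm, xNorm = xNorm, z = z, comp = comp, clus = clus)
  })
  if (!is.null(prep$comp)) {
    writeTsv(prep$comp, file.path(stage, "composite_z.tsv"))
  }
  writeTsv(data.frame(position = seq_along(prep$clus$labels),
                      sample_id = prep$clus$labels, stringsAsFactors = FALSE),
           file.path(stage, "sample_cluster_order.tsv"))

  pca <- runStage("pca", runPCA(prep$z, k = 2L))
  writeTsv(data.frame(component = seq_along(pca@varianceExplained),
                      variance_fraction = pca@varianceExplained),
           file.path(stage, "pca_variance.tsv"))
  writeTsv(data.frame(sample_id = rownames(prep$z),
                      pc1 = pca@scores[, 1], pc2 = pca@scores[, 2],
                      stringsAsFactors = FALSE),
           file.path(stage, "pca_scores.tsv"))

  periods <- periodLabels(me)
  iAC <- periods %in% c("A", "C")
  mv <- runStage("multivariate", {
    xAC <- prep$xNorm[iAC, , drop = FALSE]
    yAC <- periods[iAC]
    # latent-variable models on the same scale as the Z-scores;
    # fold changes always on raw normalized means
    xMult <- if (config$log2BeforeZscore) log2(xAC + 1) else xAC
    model <- fitOplsda(xMult, yAC, nOrtho = config$nOrtho,
                       scaling = config$scaling)
    validation <- validateOplsda(xMult, yAC, nFolds = config$nFolds,
                                 nPerm = config$nPerm,
                                 seed = substreamSeed(config$seed, "oplsda"),
                                 nOrtho = config$nOrtho,
                                 scaling = config$scaling)
    uni <- univariateStats(xAC, yAC)
    imp <- rfImportance(xAC, yAC, nTrees = config$nTrees,
                        seed = substreamSeed(config$seed, "rf"))
    diffTab <- differentialTable(vipScores(model), uni, imp,
                                 vipCutoff = config$vipCutoff)
    list(model = model, validation = validation, uni = uni,
         importance = imp, diffTab = diffTab)
  })
  v <- mv$validation
  jsonlite::write_json(
    list(R2Y_cum = r2y(mv$model), Q2_cum = q2(v), RMSEE = rmsee(mv$model),
         perm_p_R2Y = v@permPR2Y, perm_p_Q2 = v@permPQ2,
         n_permutations = v@nPerm,
         cvanova_F = v@cvF, cvanova_p = v@cvP, cvanova_eta2 = v@cvEta2,
         n_folds = v@nFolds, seed = v@seed),
    file.path(stage, "validation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeTsv(mv$diffTab, file.path(stage, "differential.tsv"))

  nets <- runStage("networks", {
    perPeriod <- lapply(c(A = "A", B = "B", C = "C"), function(p) {
      xs <- prep$xNorm[periods == p, , drop = FALSE]
      buildPeriodNetwork(pairwiseCorrelations(xs, method = config$corMethod),
                         rThreshold = config$rThreshold,
                         fdrCutoff = config$fdrCutoff, period = p)
    })
    core <- coreNetwork(perPeriod$A, perPeriod$B, perPeriod$C, mode = "edge")
    fn <- lapply(perPeriod, function(nt) firstNeighbors(core, nt))
    list(perPeriod = perPeriod, core = core, firstNeighbors = fn)
  })
  allNets <- c(nets$perPeriod, list(core = nets$core),
               stats::setNames(nets$firstNeighbors,
                               paste0("first_neighbors_", names(nets$firstNeighbors))))
  dir.create(file.path(stage, "networks"), showWarnings = FALSE)
  for (nm in names(allNets)) {
    exportNetwork(allNets[[nm]],
                  file.path(stage, "networks", paste0(nm, ".sif")), "sif")
    exportNetwork(allNets[[nm]],
                  file.path(stage, "networks", paste0(nm, ".graphml")), "graphml")
  }
  metrics <- lapply(allNets, function(nt) {
    if (length(networkNodes(nt)) == 0L) NULL else topologyMetrics(nt)
  })
  jsonlite::write_json(
    lapply(metrics, function(m) if (is.null(m)) NULL else as.list(m)),
    file.path(stage, "network_metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  assoc <- runStage("growth_association", {
    ratio <- allometricRatio(birds$liver_mass_g, birds$body_mass_g)
    rbind(
      growthAssociation(prep$xNorm, ratio, "allometric_ratio",
                        method = config$corMethod),
      growthAssociation(prep$xNorm, birds$liver_mass_g, "liver_mass",
                        method = config$corMethod)
    )
  })
  writeTsv(assoc, file.path(stage, "growth_associations.tsv"))

  xeno <- annotateXenometabolites(colnames(prep$xNorm))
  writeTsv(xeno, file.path(stage, "xenometabolites.tsv"))

  yaml::write_yaml(configEcho(config), file.path(stage, "config_echo.yaml"))
  note("pipeline complete")
  writeLines(logLines, file.path(stage, "run.log"))

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage, recursive = TRUE)) {
    dir.create(dirname(file.path(config$outdir, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(stage, f), file.path(config$outdir, f),
              overwrite = TRUE)
  }
  ok <- TRUE
  unlink(stage, recursive = TRUE)

  bundle <- list(
    growthSummary = gs, phase = phase, compositeZ = prep$comp,
    clusterOrder = prep$clus$labels, pca = pca,
    model = mv$model, validation = mv$validation,
    univariate = mv$uni, importance = mv$importance,
    differential = mv$diffTab,
    networks = allNets, metrics = metrics, associations = assoc,
    xenometabolites = xeno,
    truth = if (config$synthetic) study$truth else NULL,
    outdir = config$outdir, config = config
  )
  class(bundle) <- "ReportBundle"
  invisible(bundle)
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle\n")
  cat(sprintf("  output: %s\n", x$outdir))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f, RMSEE = %.3f\n",
              r2y(x$model), q2(x$validation), rmsee(x$model)))
  cat(sprintf("  CV-ANOVA F = %.1f (p = %.3g, Eta2 = %.2f)\n",
              x$validation@cvF, x$validation@cvP, x$validation@cvEta2))
  cat(sprintf("  differential metabolites (VIP > %g): %d\n",
              x$config$vipCutoff, nrow(x$differential)))
  cat(sprintf("  core network: %d nodes, %d edges\n",
              length(networkNodes(x$networks$core)),
              nrow(networkEdges(x$networks$core))))
  invisible(x)
}
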