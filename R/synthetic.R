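# Synthetic-study generator. Emulates the study design the pipeline
# assumes: 9 even necropsy days (4-20), 12 birds per day, 204 named
# metabolites, opposing early/late planted mean shifts, persistent
# high-correlation metabolite cliques and sporadically detected
# xenometabolites. Everything downstream is testable against the planted
# truth without real data.

#' Configuration for a synthetic post-hatch liver study
#'
#' Defaults reproduce the design the pipeline targets: even days 4-20,
#' 12 birds per day, 204 named metabolites, a standardized early-vs-late
#' shift of 2 pooled SD units for the two signature metabolite groups, one
#' persistent 5-member correlation clique at loading 0.95 and a handful of
#' zero-inflated xenometabolite columns.
#'
#' Signal model (all on the natural-log scale; peak heights are strictly
#' positive and right-skewed, so baselines are log-normal): for metabolite j
#' in sample i, `log x_ij = mu_j + delta_j(day_i) + a f_i + s e_ij`.
#' `delta` is a linear-in-day ramp arranged so the period A mean minus the
#' period C mean equals `effectSizeD * noiseSd` for group 1 (and the
#' negative for group 2), making both Cohen's d and log2 fold change
#' controlled. Clique members share a standard-normal per-sample latent
#' factor `f` with loading `a` and residual SD `cliqueResidSd`, giving an
#' expected pairwise log-scale correlation of `a^2 / (a^2 + s^2)`.
#' Xenometabolite columns are Bernoulli-detected with log-normal magnitude.
#'
#' @param days necropsy days (ascending, within 1-30; default even 4-20).
#' @param birdsPerDay birds necropsied per day (>= 2; default 12).
#' @param nMetabolites number of named metabolites (default 204).
#' @param group1,group2 metabolite names elevated in period A / period C
#'   respectively (disjoint).
#' @param effectSizeD standardized A-vs-C mean shift (>= 0; default 2).
#' @param coreCliques list of `list(members = <names>, loading = a)` with
#'   `a` in (0, 1); members share a per-sample latent factor in every period.
#' @param cliqueResidSd residual log-scale SD for clique members (default
#'   0.15, so the default loading 0.95 yields pairwise r of about 0.98).
#' @param xenoNames names of sporadically detected xenometabolite columns.
#' @param xenoDetectProb per-sample detection probability for xenometabolite
#'   columns (default 0.3).
#' @param ratioCoupled optional `list(name = <metabolite>, loading = a)`:
#'   that metabolite loads on each bird's standardized allometric ratio
#'   (residual SD `sqrt(1 - a^2)`), for growth-association recovery tests.
#' @param noiseSd residual log-scale SD for ordinary metabolites (> 0).
#' @param baselineLogMean,baselineLogSd log-normal baseline parameters.
#' @param growthCV multiplicative (log-scale SD) noise on body and liver
#'   masses (>= 0; default 0.07).
#' @param seed integer master seed; stage substreams are derived from it.
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(days = seq(4L, 20L, by = 2L),
                            birdsPerDay = 12L,
                            nMetabolites = 204L,
                            group1 = c("myristic acid", "oleic acid",
                                       "palmitic acid", "1-monopalmitin",
                                       "alpha-tocopherol"),
                            group2 = c("adenine", "glucose-6-phosphate",
                                       "hexose-6-phosphate", "aspartic acid",
                                       "fucose"),
                            effectSizeD = 2,
                            coreCliques = list(list(
                              members = c("valine", "isoleucine", "leucine",
                                          "methionine", "succinic acid"),
                              loading = 0.95)),
                            cliqueResidSd = 0.15,
                            xenoNames = c("benzoic acid", "pyrogallol",
                                          "nornicotine", "maleimide",
                                          "levoglucosan"),
                            xenoDetectProb = 0.3,
                            ratioCoupled = NULL,
                            noiseSd = 1,
                            baselineLogMean = log(1e5),
                            baselineLogSd = 1,
                            growthCV = 0.07,
                            seed = 1L) {
  days <- as.integer(days)
  if (is.unsorted(days, strictly = TRUE)) stop("'days' must be strictly ascending")
  if (any(days < 1L | days > 30L)) stop("'days' must lie within 1-30")
  if (birdsPerDay < 2L) stop("'birdsPerDay' must be >= 2")
  assertScalarNumber(effectSizeD, "effectSizeD", lower = 0)
  assertScalarNumber(noiseSd, "noiseSd")
  if (noiseSd <= 0) stop("'noiseSd' must be > 0")
  assertScalarNumber(cliqueResidSd, "cliqueResidSd")
  if (cliqueResidSd <= 0) stop("'cliqueResidSd' must be > 0")
  assertScalarNumber(xenoDetectProb, "xenoDetectProb", lower = 0, upper = 1)
  assertScalarNumber(growthCV, "growthCV")
  if (growthCV < 0) stop("'growthCV' must be >= 0")
  if (length(intersect(group1, group2))) stop("group1 and group2 must be disjoint")
  cliqueMembers <- unlist(lapply(coreCliques, `[[`, "members"))
  for (cl in coreCliques) {
    a <- cl$loading
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1) {
      stop("clique loadings must lie in (0, 1)")
    }
    if (length(cl$members) < 2L) stop("cliques need at least two members")
  }
  coupledName <- if (!is.null(ratioCoupled)) ratioCoupled$name else character(0)
  if (!is.null(ratioCoupled)) {
    a <- ratioCoupled$loading
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1) {
      stop("'ratioCoupled$loading' must lie in (0, 1)")
    }
  }
  planted <- c(group1, group2, cliqueMembers, xenoNames, coupledName)
  if (anyDuplicated(planted)) {
    stop("planted metabolite names (groups, cliques, xenometabolites, ",
         "ratio-coupled) must be distinct")
  }
  if (length(planted) > nMetabolites) {
    stop("more planted metabolites than 'nMetabolites'")
  }
  filler <- sprintf("metabolite_%03d", seq_len(nMetabolites))
  filler <- setdiff(filler, planted)
  metabolites <- c(planted, filler)[seq_len(nMetabolites)]
  cfg <- list(days = days, birdsPerDay = as.integer(birdsPerDay),
              nMetabolites = as.integer(nMetabolites),
              group1 = group1, group2 = group2, effectSizeD = effectSizeD,
              coreCliques = coreCliques, cliqueResidSd = cliqueResidSd,
              xenoNames = xenoNames, xenoDetectProb = xenoDetectProb,
              ratioCoupled = ratioCoupled, noiseSd = noiseSd,
              baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
              growthCV = growthCV, seed = as.integer(seed),
              metabolites = metabolites)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Allometric-ratio and body-mass templates
#'
#' The noise-free trajectories the growth generator is built on. Body mass
#' follows a Gompertz curve (monotone increasing, broiler-like: ~100 g at
#' day 4, ~1.1 kg at day 20). The allometric ratio rises from day 4 to 6,
#' falls through day 12, briefly rises to day 14, then falls again —
#' the piecewise shape that defines the A/B/C periods.
#'
#' @param days integer vector of days in 1..30 (the ratio anchors cover
#'   4-20; outside that range the nearest anchor value is carried over).
#' @return data.frame with columns `day`, `body_g`, `ratio`.
#' @export
growthTemplate <- function(days) {
  anchorDays <- seq(4L, 20L, by = 2L)
  anchorRatio <- c(0.0280, 0.0320, 0.0295, 0.0268, 0.0262,
                   0.0285, 0.0272, 0.0258, 0.0246)
  if (any(days < 1 | days > 30)) stop("template defined for days 1-30")
  ratio <- stats::approx(anchorDays, anchorRatio, xout = days, rule = 2)$y
  body <- 5000 * exp(-4.97 * exp(-0.06 * days))
  data.frame(day = as.integer(days), body_g = body, ratio = ratio)
}

#' Generate bird growth records
#'
#' Body mass follows the monotone Gompertz template with multiplicative
#' log-normal noise; liver mass is the template allometric ratio times body
#' mass, again with multiplicative noise. With `growthCV = 0` every bird on
#' a day has identical masses and the ratio equals the template exactly.
#'
#' @param config a [syntheticConfig()].
#' @return data.frame of bird records: `sample_id`, `bird_id`, `day`,
#'   `body_mass_g`, `liver_mass_g`.
#' @export
generateGrowth <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  tpl <- growthTemplate(config$days)
  withSeed(substreamSeed(config$seed, "growth"), {
    rows <- lapply(seq_along(config$days), function(k) {
      d <- config$days[k]
      body <- tpl$body_g[k] * exp(stats::rnorm(config$birdsPerDay, 0, config$growthCV))
      liver <- tpl$ratio[k] * body * exp(stats::rnorm(config$birdsPerDay, 0, config$growthCV))
      data.frame(
        sample_id = sprintf("D%02d_B%02d", d, seq_len(config$birdsPerDay)),
        bird_id = sprintf("bird_%02d_%02d", d, seq_len(config$birdsPerDay)),
        day = d, body_mass_g = body, liver_mass_g = liver,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' @noRd
periodRamp <- function(days, effectSizeD, noiseSd) {
  # linear-in-day ramp, zero at day 18 (period C mean day), scaled so the
  # mean over period A days minus the mean over period C days equals
  # effectSizeD * noiseSd exactly
  effectSizeD * noiseSd * (18 - days) / 12
}

#' Generate a complete synthetic study
#'
#' Draws growth records and the peak-height matrix under the signal model
#' described in [syntheticConfig()]. Fully reproducible: the same config
#' (including seed) gives a bit-identical study. Growth and matrix use
#' named substreams of the master seed so each is reproducible on its own.
#'
#' @param config a [syntheticConfig()].
#' @return list of class `"StudyData"`: `birds` (growth records),
#'   `experiment` (a [MetabolomeExperiment-class], samples = days x birds),
#'   `truth` (planted parameters for recovery tests) and `config`.
#' @examples
#' study <- generateStudy(syntheticConfig(seed = 7))
#' dim(metaboliteMatrix(study$experiment)) # 108 x 204
#' @export
generateStudy <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  birds <- generateGrowth(config)
  n <- nrow(birds)
  mets <- config$metabolites
  m <- length(mets)
  ratio <- allometricRatio(birds$liver_mass_g, birds$body_mass_g)
  zratio <- if (stats::sd(ratio) > 0) (ratio - mean(ratio)) / stats::sd(ratio) else ratio * 0

  values <- withSeed(substreamSeed(config$seed, "matrix"), {
    mu <- stats::rnorm(m, config$baselineLogMean, config$baselineLogSd)
    names(mu) <- mets
    logx <- matrix(rep(mu, each = n), nrow = n, dimnames = list(birds$sample_id, mets))
    ramp <- periodRamp(birds$day, config$effectSizeD, config$noiseSd)
    for (g in config$group1) logx[, g] <- logx[, g] + ramp
    for (g in config$group2) logx[, g] <- logx[, g] - ramp
    residSd <- stats::setNames(rep(config$noiseSd, m), mets)
    for (cl in config$coreCliques) {
      f <- stats::rnorm(n)
      for (g in cl$members) {
        logx[, g] <- logx[, g] + cl$loading * f
        residSd[g] <- config$cliqueResidSd
      }
    }
    if (!is.null(config$ratioCoupled)) {
      a <- config$ratioCoupled$loading
      g <- config$ratioCoupled$name
      logx[, g] <- logx[, g] + a * zratio
      residSd[g] <- sqrt(1 - a^2)
    }
    noise <- matrix(stats::rnorm(n * m), nrow = n)
    logx <- logx + sweep(noise, 2, residSd, `*`)
    x <- exp(logx)
    if (length(config$xenoNames)) {
      detected <- matrix(
        stats::rbinom(n * length(config$xenoNames), 1L, config$xenoDetectProb),
        nrow = n)
      x[, config$xenoNames] <- x[, config$xenoNames] * detected
    }
    x
  })

  meta <- data.frame(
    bird_id = birds$bird_id, day = birds$day,
    period = vapply(birds$day, assignPeriod, character(1), strict = FALSE),
    body_mass_g = birds$body_mass_g, liver_mass_g = birds$liver_mass_g,
    stringsAsFactors = FALSE
  )
  rownames(meta) <- birds$sample_id
  experiment <- MetabolomeExperiment(values, meta, normalized = FALSE,
                                     strictPeriods = FALSE)
  truth <- list(
    group1 = config$group1, group2 = config$group2,
    differential = c(config$group1, config$group2),
    cliques = config$coreCliques,
    xenometabolites = config$xenoNames,
    ratioCoupled = config$ratioCoupled,
    effectSizeD = config$effectSizeD
  )
  structure(list(birds = birds, experiment = experiment,
                 truth = truth, config = config),
            class = "StudyData")
}

#' @export
print.StudyData <- function(x, ...) {
  cat(sprintf("StudyData: %d birds over days %s; %d metabolites\n",
              nrow(x$birds), paste(range(x$birds$day), collapse = "-"),
              x$config$nMetabolites))
  invisible(x)
}
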