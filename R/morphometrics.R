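# Morphometrics: allometric ratios, growth-period assignment and
# allometric phase-sign detection from bird mass records.

#' Allometric liver ratio
#'
#' Ratio of liver mass to total body mass, the quantity whose trajectory
#' defines the three post-hatch growth periods.
#'
#' @param liverMass liver mass in grams (> 0), vectorized.
#' @param bodyMass body mass in grams (> 0), vectorized.
#' @return dimensionless ratio(s); in (0, 1) for anatomically valid records.
#' @examples
#' allometricRatio(2, 100) # 0.02
#' @export
allometricRatio <- function(liverMass, bodyMass) {
  if (any(!is.finite(liverMass)) || any(!is.finite(bodyMass)) ||
      any(liverMass <= 0) || any(bodyMass <= 0)) {
    stop("masses must be positive and finite")
  }
  liverMass / bodyMass
}

#' Assign a post-hatch day to a growth period
#'
#' Period A covers days 4, 6, 8; period B days 10, 12, 14; period C days
#' 16, 18, 20. In lenient mode off-schedule days are binned as 4-9 -> A,
#' 10-15 -> B, 16-20 -> C (real necropsy data can include odd days).
#'
#' @param day integer day post-hatch.
#' @param strict if TRUE (default) `day` must be an even day in 4..20.
#' @return one of "A", "B", "C".
#' @examples
#' assignPeriod(4)            # "A"
#' assignPeriod(14)           # "B"
#' assignPeriod(9, strict = FALSE) # "A"
#' @export
assignPeriod <- function(day, strict = TRUE) {
  if (length(day) != 1L || !is.finite(day)) stop("'day' must be a single number")
  day <- as.integer(day)
  if (strict) {
    if (!day %in% seq(4L, 20L, by = 2L)) {
      stop(sprintf("day %d is outside the study schedule (even days 4-20)", day))
    }
  } else if (day < 4L || day > 20L) {
    stop(sprintf("day %d is outside the covered range 4-20", day))
  }
  if (day <= 9L) "A" else if (day <= 15L) "B" else "C"
}

#' Per-day growth summary
#'
#' Mean and SD of body mass, liver mass and allometric ratio for each
#' necropsy day.
#'
#' @param birds data.frame with columns `bird_id`, `day`, `body_mass_g`,
#'   `liver_mass_g` (one row per bird).
#' @return data.frame with one row per distinct day (ascending), columns
#'   `day`, `n`, `body_mean`, `body_sd`, `liver_mean`, `liver_sd`,
#'   `ratio_mean`, `ratio_sd`.
#' @export
growthSummary <- function(birds) {
  need <- c("day", "body_mass_g", "liver_mass_g")
  if (!all(need %in% colnames(birds))) {
    stop(sprintf("'birds' needs columns %s", paste(need, collapse = ", ")))
  }
  if (any(birds$body_mass_g <= 0) || any(birds$liver_mass_g <= 0)) {
    stop("masses must be positive")
  }
  if (any(birds$liver_mass_g >= birds$body_mass_g)) {
    stop("liver mass must be smaller than body mass")
  }
  ratio <- allometricRatio(birds$liver_mass_g, birds$body_mass_g)
  days <- sort(unique(birds$day))
  out <- do.call(rbind, lapply(days, function(d) {
    i <- birds$day == d
    data.frame(
      day = d, n = sum(i),
      body_mean = mean(birds$body_mass_g[i]), body_sd = sd0(birds$body_mass_g[i]),
      liver_mean = mean(birds$liver_mass_g[i]), liver_sd = sd0(birds$liver_mass_g[i]),
      ratio_mean = mean(ratio[i]), ratio_sd = sd0(ratio[i])
    )
  }))
  rownames(out) <- NULL
  out
}

#' @noRd
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Allometric phase signs between consecutive days
#'
#' Sign of the difference of consecutive day-mean allometric ratios.
#' Positive phases mark intervals where the liver grows faster than the
#' body; differences smaller in magnitude than `tol` are called flat.
#'
#' @param summary a [growthSummary()] data.frame (>= 2 days).
#' @param tol absolute tolerance on the ratio scale below which an interval
#'   is flat (default 1e-6).
#' @return character vector of "positive"/"negative"/"flat", named
#'   "d1-d2" for each consecutive day pair.
#' @examples
#' gs <- data.frame(day = c(4, 6, 8), n = 1,
#'                  body_mean = 1, body_sd = 0, liver_mean = 1, liver_sd = 0,
#'                  ratio_mean = c(0.028, 0.032, 0.029), ratio_sd = 0)
#' allometricPhase(gs)
#' @export
allometricPhase <- function(summary, tol = 1e-6) {
  if (nrow(summary) < 2L) stop("at least two days are needed to define a phase")
  assertScalarNumber(tol, "tol", lower = 0)
  d <- diff(summary$ratio_mean)
  out <- ifelse(abs(d) < tol, "flat", ifelse(d > 0, "positive", "negative"))
  names(out) <- paste(summary$day[-nrow(summary)], summary$day[-1L], sep = "-")
  out
}

#' Read a bird metadata table
#'
#' @param path TSV with columns `sample_id`, `bird_id`, `day`,
#'   `body_mass_g`, `liver_mass_g` (as written by [writeStudy()]).
#' @return data.frame of bird records.
#' @export
readSamples <- function(path) {
  if (!file.exists(path)) stop(sprintf("samples file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "day", "body_mass_g", "liver_mass_g")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop(sprintf("samples file %s lacks columns: %s", path,
                 paste(miss, collapse = ", ")))
  }
  df
}
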