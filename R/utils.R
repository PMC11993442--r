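# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers never perturb the global
#' random stream. All randomness in the package funnels through this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed from a master seed
#'
#' Each pipeline stage draws from its own substream so stages stay
#' independently reproducible. Deterministic string hash folded into the
#' master seed; result kept inside the 32-bit integer range.
#'
#' @keywords internal
#' @noRd
substreamSeed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1998244353
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483629L)
}

#' @noRd
assertScalarNumber <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 what, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
fmtNum <- function(x) {
  # full-precision, locale-independent text form used by all writers so that
  # artifacts are byte-identical across runs
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
}
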