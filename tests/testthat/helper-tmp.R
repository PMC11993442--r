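# Small conveniences for tests.

withr_like_tempdir <- function() {
  d <- tempfile("allomet_test_")
  dir.create(d, recursive = TRUE)
  d
}

# random samples x metabolites matrix with names
randomMatrix <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("s%02d", seq_len(n)),
                         sprintf("m%02d", seq_len(m))))
}
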