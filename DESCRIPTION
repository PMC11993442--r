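Package: allomet
Title: Allometric Growth and Metabolome Network Analysis of the Post-Hatch
    Chicken Liver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for untargeted GC-TOF metabolomics of the
    post-hatch chicken liver. Segments early growth into three periods from
    the allometric liver ratio, discriminates early and late periods with
    orthogonal partial least squares discriminant analysis (O-PLS-DA)
    validated by permutation testing, cross-validated Q2 and CV-ANOVA,
    computes per-metabolite differential statistics (VIP, log2 fold change,
    Cohen's d, random-forest importance, FDR), and builds per-period
    correlation networks whose intersection defines a core metabolite
    network with first-neighbor expansion and topology metrics. Includes a
    synthetic-study generator with planted effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    xml2,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
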