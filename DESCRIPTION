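Package: cyclerelax
Title: Branch Codon Models and Selection-Intensity Tests for Life-Cycle
    Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale tests for life-cycle-dependent molecular evolution
    in aphids. Implements GY94-style codon substitution models with
    branch-class-specific dN/dS, Felsenstein pruning likelihoods, maximum
    likelihood fits of two- and three-ratio branch models with likelihood
    ratio tests and Benjamini-Hochberg correction, a RELAX-style
    selection-intensity test (k parameter on test branches over a three
    category site model), codon-aware alignment cleaning (coverage,
    codon-gappy trimming, ambiguity homogenization, consensus z-score
    divergence filtering), hypergeometric GO term enrichment, and a seeded
    codon-evolution simulator that generates alignments, labeled trees,
    trait tables and GO maps with the statistical structure the analysis
    assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
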