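Package: xoinv
Title: Counting Models of Breakpoint-Chiasma Interference in Pericentric
    Inversion Heterokaryotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a single-pathway counting model of chiasma
    interference for chromosomes carrying a pericentric inversion in
    heterozygous state, where the inversion breakpoints may themselves
    interfere with nearby chiasma formation.  Computes multilocus
    recombination-pattern probabilities by phase-matrix multiplication,
    conditions them on gamete viability (balanced gametes only), and
    provides closed-form heterokaryotype sterility.  Includes maximum
    likelihood fitting of the competing interference hypotheses by
    multi-start Nelder-Mead, AIC and likelihood-ratio model comparison,
    parametric-bootstrap confidence intervals, a least-squares sterility
    fit across inversions, and an exact Monte-Carlo meiosis simulator
    that doubles as a synthetic-data generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
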