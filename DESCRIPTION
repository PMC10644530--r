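Package: genebirth
Title: Forward-Time Simulation of Non-Genic Locus Adaptation and De Novo
    Gene Birth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time population-genetic simulator for the adaptation
    of a single non-genic locus, the process underlying de novo gene
    birth. Mutational fitness effects follow a four-parameter two-sided
    gamma distribution of fitness effects (DFE); populations of haploid,
    asexually reproducing individuals evolve under either a high or a low
    mutation-rate regime, with optional whole-locus deletion by
    structural variation. The locus fitness contribution decomposes into
    an adaptive value and an expression level (F = A * E), with
    mutational effects on expression drawn from a bounded power law.
    Provides analytic and Monte-Carlo characterisation of DFEs,
    last-common-ancestor tracing to detect fixation, replicate ensembles
    and parameter sweeps (conducivity, locus loss and retention,
    trajectory summaries), and tail-shape model selection (exponential
    versus power law) for mutational effects on adaptive value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
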