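Package: swarmlr
Title: Fish-Swarm Logic Regression for Detecting Interacting SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sets of interacting single nucleotide polymorphisms (SNPs)
    that jointly explain a binary case-control phenotype using fish-swarm logic
    regression (FSLR): a school of fish agents, each holding a Boolean logic-tree
    regression model, searches the model space in parallel with preset agent and
    swarm behaviors, out-of-bag SNP importance measures, a Metropolis-style
    acceptance rule, and stepwise partial-F elimination. Includes a case-control
    haplotype simulator with planted causal Boolean expressions, risk and noise
    levels, and the accuracy metrics (type I/II error rates, identified-causal
    counts) needed to reproduce simulation studies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
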