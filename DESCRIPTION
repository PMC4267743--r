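Package: meiotest
Title: Hypothesis Testing of Meiotic Recombination Rates from Population Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-ratio testing for the presence of crossover and gene
    conversion from phased population SNP haplotypes. Implements a
    product-of-approximate-conditionals (PAC) copying likelihood whose hidden
    copying process interleaves a crossover chain with a gene-conversion tract
    chain, maximum a posteriori estimation of the population-scaled crossover
    rate, conversion initiation rate, and mean conversion tract length by
    Nelder-Mead search, and a parametric bootstrap calibration of the
    boundary-null likelihood-ratio statistic (gamma = 0, no gene conversion;
    or rho = 0, no crossover), for which the usual chi-squared asymptotics
    fail. Includes a back-in-time coalescent simulator with crossover,
    gene conversion and infinite-sites mutation used for bootstrap
    resampling and simulation studies, plus readers and writers for
    ms-format haplotype data and overlapping-window segmentation of loci.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
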