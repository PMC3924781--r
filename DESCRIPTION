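Package: dbxqtl
Title: Mixed-Model Composite Interval Mapping for Immortal Double Backcross Populations
Version: 0.1.0
Authors@R: person("dbxqtl", "developers", role = c("aut", "cre"),
    email = "dbxqtl@example.org")
Description: QTL linkage mapping for immortal double backcross populations,
    i.e. progeny obtained by crossing a panel of doubled-haploid (DH) or
    selfed recombinant-inbred (RI) lines to both homozygous parents.  The
    design supports estimation of additive, dominance and additive-additive
    epistatic QTL effects together with their environment interactions under
    a mixed linear model.  The package provides the conditional QTL-genotype
    probability kernel for both backcross sides, a gamete-level population
    and phenotype simulator with heritability calibration, Henderson method
    III F-tests for fixed QTL-effect blocks, composite-interval 1D and 2D
    genome scans with marker-pair cofactor pre-selection and permutation
    thresholds, Gibbs-sampling estimation of genetic effects and variance
    components, and a Monte Carlo harness for power, bias and false
    discovery rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
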