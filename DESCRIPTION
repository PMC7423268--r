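Package: barrierflow
Title: Genetic Barriers to Gene Flow in Continent-Island
    Migration-Selection Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic multilocus population-genetic models of a
    continent-island pair connected by one-way migration.  Represents
    diallelic fitness landscapes with arbitrary epistasis (haploid, or
    diploid with codominant or recessive incompatibilities), integrates
    the haplotype-frequency dynamics under selection, migration and
    recombination (continuous time, linkage-equilibrium and tight-linkage
    limits, and a discrete-time variant), and measures the strength of a
    genetic barrier to gene flow as the maximum sustainable migration
    rate (m_max).  Companion measures of local adaptation (current Lambda
    and the maximum Lambda_max over admissible evolutionary histories)
    allow barriers to be classified as weak (m_max <= Lambda_max) or
    strong, including the minimal three-locus cryptic-epistasis
    configuration in which reproductive isolation exceeds the limit set
    by ecological differentiation.  Closed-form results are provided as
    independent oracles for the numerical machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
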