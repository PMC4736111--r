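Package: ldphase
Title: Linkage Disequilibrium Decay, Persistence of Phase and Effective
    Population Size from Phased SNP Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of phased SNP-array data
    in livestock populations: pairwise signed r and Hill-Robertson r-squared
    computed from gametic haplotype frequencies, genome-wide LD decay with
    distance binning, marker-panel thinning experiments, analysis-of-covariance
    models of LD heterogeneity across chromosomes and breeds with least-squares
    means and predicted r-squared at commercial-panel marker spacings,
    across-population persistence of linkage phase (correlation of signed r),
    and historical effective population size estimated from distance-stratified
    LD via E(r2) = 1/(4cNe+1). Includes SNP and sample quality control
    mirroring standard array filters, phased-VCF and plain-text haplotype I/O,
    and a forward Wright-Fisher simulator with recombination, admixture and
    array-style marker ascertainment that provides ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
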