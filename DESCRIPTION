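Package: cytosym
Title: Co-Inheritance Analysis of Endosymbiont and Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying maternally co-inherited cytoplasmic genomes
    (an endosymbiont such as Wolbachia, and host mitochondrial DNA) from
    whole-genome shotgun data. Implements infection calling from depth and
    breadth of coverage, consensus building from per-site base counts,
    relative copy-number estimation, ungapped partitioned alignments,
    neighbor-joining genealogies with bootstrap support, HKY+Gamma
    partitioned likelihoods on fixed topologies, a single- versus
    two-topology congruence test compared by AIC and log10 Bayes factors,
    fixed-topology Bayesian dating with a lognormal mutation-rate
    calibration prior and discrete phylogeography, population-genetic
    statistics (pi, Watterson's theta, Tajima's D with a
    conditional-on-S coalescent null, a patristic Kst permutation test),
    and in silico marker genotyping (IS5 insertion junctions, diagnostic
    mtDNA SNPs, COI haplotypes). A coalescent-based synthetic-data
    generator emulating imperfect maternal transmission makes every stage
    testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    Matrix,
    jsonlite,
    data.table,
    seqinr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
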