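Package: riverscan
Title: Convergence Detection in Replicated High- and Low-Predation Population Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting convergent evolution across
    replicated high-predation/low-predation (HP/LP) population pairs of
    riverine fish. Provides a forward Wright-Fisher simulator with founding
    bottlenecks, downstream-biased migration and plantable selective-sweep
    haplotypes; windowed selection scans (absolute allele frequency
    difference, Hudson FST with pseudo-observed-data thresholds, XP-EHH);
    multi-scan outlier intersection and cross-river overlap summaries;
    weighted permutation tests for pathway-level convergence; local-PCA/MDS
    ancestry deviation; haplogroup calling and windowed BIONJ branch-length
    contrasts; folded two-dimensional site-frequency spectra with
    hypergeometric projection; and Patterson's D / f4-ratio introgression
    screening with block-jackknife significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
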