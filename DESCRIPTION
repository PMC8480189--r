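Package: parinv
Title: Parallel Freshwater Adaptation and Chromosomal Inversion Scans from
    Population Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting signatures of parallel adaptation and
    putative chromosomal inversions from diploid biallelic SNP genotypes in
    an ancestral-versus-derived population design. Implements SNP filtering
    from VCF input, heterozygosity and Weir-Cockerham FST statistics, dual
    divergence-outlier scans (Fisher's exact test and a PCA-based
    Mahalanobis statistic) with all-pairs intersection, favored-allele
    frequency-shift summaries, linkage-disequilibrium network clustering
    for single-outlier cluster (inversion candidate) detection, PCA-based
    inversion karyotyping, and a population genotype simulator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
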