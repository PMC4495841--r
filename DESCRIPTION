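Package: lofscape
Title: Worldwide Loss-of-Function Landscape of the OCT1 Drug Transporter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of loss of activity of the hepatic
    organic cation transporter OCT1 (SLC22A1). Provides packaged worldwide
    star-allele frequency fixtures, EM-based haplotype phasing of unphased
    coding genotypes, star-allele naming and activity-threshold classification
    of alleles and diplotypes, functionally stratified diversity statistics
    (segregating sites, nucleotide diversity, Watterson's theta, Tajima's D
    with coalescent null simulation), hierarchical analysis of molecular
    variance (AMOVA) with Phi statistics and permutation tests, pairwise
    F_ST matrices, exact multinomial outlier-population probabilities, and a
    Hardy-Weinberg diplotype simulator with truth tracking for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
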