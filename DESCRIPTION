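Package: patchkin
Title: Kin Structure, Null Alleles and Fine-Scale Differentiation from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting family structure and chaotic genetic
    patchiness in high-dispersal marine populations genotyped at
    co-dominant microsatellite loci. Provides GenePop and long-form CSV
    input/output, per-locus diversity summaries, Hardy-Weinberg exact
    tests (full enumeration and Markov-chain), genotypic linkage
    disequilibrium tests, Weir-Cockerham F-statistics with randomization
    significance, moment and EM estimation of null-allele frequencies
    with deterministic genotype adjustment, maximum-likelihood dyadic
    relatedness with relationship classification (unrelated, half-sib,
    full-sib, parent-offspring), permutation tests of kin aggregation,
    extended sibship-network reconstruction, and an ENA-style
    null-allele correction of F_ST. A seeded simulator generates
    microsatellite datasets with known pedigrees, inbreeding, null
    alleles and Balding-Nichols differentiation so every estimator can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
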