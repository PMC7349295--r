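Package: sexmethyl
Title: Factorial Analysis of Sex-Biased DNA Methylation from WGBS Count Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential DNA methylation analysis for factorial
    sex-genotype designs (XX females, XY females, XY males, XO females and
    XX Paf females), starting from per-CpG methylated/total count tables.
    Provides SNP masking and coverage filtering, window-smoothed Wald tests
    for differentially methylated CpG sites, two region callers (a scan
    caller with run-based output constraints and a 300 bp tile caller with
    overdispersion correction) and their union, UpSet-style set algebra to
    classify effects into sex-phenotype, X-dosage and Y-linked classes,
    CpG-island/genic/chromatin-state annotation, distance-matched
    permutation enrichment of repeat families, methylation-expression
    integration (hypergeometric DEG enrichment and directional chi-square
    tests), mouse-human ortholog overlap tests, and a beta-binomial
    synthetic-cohort generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
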