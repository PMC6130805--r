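Package: psyprs
Title: Polygenic Risk Score Construction and Evaluation for Psychosis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pruning-and-thresholding polygenic risk scores (PRS) from
    discovery GWAS summary statistics and evaluates them in multi-centre
    case / unaffected-relative / control cohorts. Includes readers for PLINK
    bed/bim/fam and VCF hard-call genotypes, allele harmonisation between
    discovery and target datasets, variant QC (minor allele frequency,
    Hardy-Weinberg equilibrium, windowed LD pruning), ancestry principal
    components, covariate-adjusted logistic association with Nagelkerke
    pseudo-R-squared and AUC, decile odds-ratio stratification, and a
    liability-threshold simulator that generates complete synthetic study
    data (discovery statistics plus an ascertained target cohort with
    screened controls and unaffected siblings of affected probands).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
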