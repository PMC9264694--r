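Package: decafr
Title: Cell-Fraction and Tumor-Specific QTL Mapping from Combined Total and Allelic Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the DeCAF (DEconvoluted cell type Allele specific
    Function) framework for discovering cell-fraction QTLs (cfQTLs) and
    tumor-specific QTLs (tsQTLs) from bulk RNA-seq. A genotype by
    cell-fraction interaction eQTL linear model on total expression is
    combined with a beta-binomial interaction allelic-imbalance regression
    on haplotype-aggregated read counts via Stouffer's method. Includes
    phased-VCF and allelic-count ingestion, copy-number masking and
    covariates, gene-level Bonferroni plus Benjamini-Hochberg multiple
    testing, a simulation framework for power and calibration studies, and
    enrichment statistics (Storey pi1, Fisher's exact, mean-Z2 resampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
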