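Package: ecogrs
Title: Genetic Risk Scores as Ecological Predictors of Coronary Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-level analysis pipeline for candidate-gene variation and
    coronary disease. At the individual level: genotype quality control
    (call rates, Hardy-Weinberg exact test, linkage-disequilibrium r2,
    expected-dosage imputation), per-study logistic association with
    covariate adjustment, inverse-variance fixed-effect meta-analysis,
    construction of an unweighted risk-allele genetic risk score (GRS)
    with LD pruning, and prediction metrics (Nagelkerke R2, ROC AUC).
    At the population level: spatial autocorrelation of population mean
    GRS (Moran's I and Geary's C randomization tests, distance-class
    correlograms), ordinary kriging with a spherical semivariogram, and
    ecological correlation/regression of coronary event rates on mean
    GRS, allele frequencies and geography with Bonferroni outlier
    detection. A synthetic-data module generates genotype panels with
    geographic allele-frequency clines and block-wise LD, case-control
    studies from a logistic disease model, and population event-rate
    tables, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    geosphere,
    nortest,
    yaml,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape,
    metafor,
    pROC,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'GenotypeExperiment.R'
    'assoc.R'
    'ecogrs-package.R'
    'ecoreg.R'
    'grs.R'
    'io.R'
    'kriging.R'
    'pipeline.R'
    'qc.R'
    'spatial.R'
    'synthio.R'
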