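Package: namqtl
Title: Simulation, Genotype QC and QTL Mapping for Backcross Nested
    Association Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing backcross-derived nested
    association mapping (NAM) panels in inbreeding crops such as wheat.
    Provides a pedigree-faithful population simulator (Haldane meiosis,
    backcrossing and single-seed descent), SNP-array genotype quality
    control with iterative random-forest imputation, physical marker
    (re)positioning from tabular alignment hits and linkage-disequilibrium
    bins, principal-coordinate population structure, augmented-trial mixed
    models for genotype BLUEs and heritability, a Q+K mixed-model
    association scan with LD-aware significance thresholds, LD-decay-window
    QTL calling with cross-trial merging, and breeder-selection summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    igraph,
    jsonlite,
    lme4,
    ranger,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geneticMap.R'
    'gwas.R'
    'impute.R'
    'io.R'
    'methods-GenotypeData.R'
    'nam.R'
    'namqtl-package.R'
    'pipeline.R'
    'positioning.R'
    'qc.R'
    'qtl.R'
    'selection.R'
    'structure.R'
    'trial.R'
    'trialmodel.R'
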