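Package: mitoflux
Title: Mitochondrial Bioenergetics Analysis from High-Resolution
    Respirometry, Fluorometry, Enzyme Assays, qPCR and Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for tissue-homogenate mitochondrial physiology
    experiments. Converts oxygen concentration traces from
    substrate-uncoupler-inhibitor titration (SUIT) respirometry into
    per-state fluxes with residual-oxygen-consumption correction, mass-
    and citrate-synthase-specific normalization, flux control ratios and
    coupling control efficiencies; calibrates Amplex UltraRed
    fluorescence against hydrogen peroxide titrations with chemical
    background and sensitivity-drift correction to yield H2O2 fluxes and
    the H2O2/O2 flux ratio; computes citrate synthase activity from
    412 nm absorbance kinetics; derives relative gene expression by the
    delta-delta-Ct method; quantifies mitochondrial morphology from
    fluorescence micrographs (segmentation, area filter, per-cell
    metrics); and provides the matching statistical layer (ROUT outlier
    screening, t and exact Mann-Whitney tests, one-way ANOVA with Sidak
    correction). A synthetic-data module simulates every input with
    recorded ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'amplex.R'
    'cs-assay.R'
    'group-stats.R'
    'io.R'
    'methods.R'
    'mitoflux-package.R'
    'morphometry.R'
    'qpcr.R'
    'render-image.R'
    'respirometry.R'
    'simulate-trace.R'
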