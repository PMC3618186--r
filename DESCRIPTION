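Package: sedeq
Title: Sedimentation-Equilibrium Association Modeling and Circular
    Dichroism Analysis of Coiled-Coil Interactions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative biophysics of protein
    self-association and hetero-association. Implements the forward physics
    of sedimentation equilibrium for single, monomer-dimer and 2:2
    "dimer-of-dimers" association schemes, global nonlinear fitting of
    multi-speed radial absorbance scans with the conventional fix/float
    parameter scheme, chi-square profiling of dissociation constants, and
    condition-series (temperature, salt, pH) summaries. Companion circular
    dichroism reductions compute mean residue ellipticity, percent helicity
    against the length-corrected theoretical helix signal, and melting
    temperatures from the first derivative of thermal denaturation curves.
    Sequence utilities provide Henderson-Hasselbalch net charge, whole and
    windowed isoelectric points, average masses and coiled-coil heptad
    geometry. Seeded synthetic-data generators emulate every supported
    experiment so the full analysis chain is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, StructuralPrediction, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cd-analysis.R'
    'io.R'
    'methods.R'
    'sedeq-core.R'
    'sedeq-fit.R'
    'sedeq-package.R'
    'seqprops.R'
    'synthetic-data.R'
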