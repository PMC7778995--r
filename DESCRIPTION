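Package: NucleomeSim
Title: Coarse-Grained Chromosome Simulation and 3D Genome Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physics-based simulation and analysis of three-dimensional
    chromosome organization at 50-kb resolution. Implements a MiChroM-style
    coarse-grained energy landscape (polymer connectivity, spherical nuclear
    confinement, the translationally invariant ideal-chromosome term,
    chromatin type-to-type interactions and stable loops), a Langevin
    sampler producing structural ensembles, readers/writers/converters for
    the .ndb family of genome-structure formats (.ndb, .spw, .cndb, .pdb,
    .gro), ChIP-seq track binning and subcompartment annotation handling,
    export of tabulated-potential input files for an external molecular
    dynamics engine, and an in-silico Hi-C validation stack (contact maps,
    P(s) curves, compartment eigenvectors, distance-stratified map
    correlations and FISH-style distance distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'NucleomeSim-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'parameters.R'
    'energy.R'
    'epigenome.R'
    'fixtures.R'
    'hic.R'
    'ndb-io.R'
    'sampler.R'
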