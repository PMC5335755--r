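Package: disms2
Title: Database-Free Proteome-Wide Distances Between LC-MS/MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes proteome-wide distances between pairs of LC-MS/MS runs
    directly from unidentified tandem (MS2) mass spectra. Implements the DISMS2
    matching algorithm (top-n peak selection, fixed-width binning, rank-window /
    charge / precursor-ppm candidate constraints, directed no-match frequencies
    and their symmetrized run distance), three spectrum distance measures
    (cosine, angle, parametrized Hausdorff), six database-annotation comparison
    modes, PERMANOVA-based parameter optimization over factorial designs,
    average-linkage dendrograms with Newick export, and a synthetic
    multi-species MS/MS run generator with technical-replicate noise.
    Reads MGF and mzML peak lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'preprocess.R'
    'distances.R'
    'matching.R'
    'annotation-modes.R'
    'clustering.R'
    'permanova.R'
    'spectra-io.R'
    'synthetic.R'
    'cli.R'
    'disms2-package.R'
    'methods-accessors.R'
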