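Package: mzSST
Title: System Suitability Testing for LC-MS via a Mass Spectrometry Query Language
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch system suitability testing (SST) for liquid
    chromatography-mass spectrometry. Implements a query-language engine
    over open-format (mzML) runs supporting per-scan filtering on precursor
    m/z, product m/z, neutral loss and retention-time windows with ppm or
    absolute tolerances; builds extracted ion chromatograms and integrates
    chromatographic peaks; computes longitudinal retention-time and
    peak-area statistics across runs; profiles MS/MS product-ion and
    neutral-loss consistency by activation type and collision energy; and
    flags instrument-performance deficiencies (missing analytes,
    retention-time shifts, elution-order inversions). Exact-mass arithmetic
    is deuterium-aware, and a deterministic synthetic-run generator
    emulating a six-analyte deuterated-acylcarnitine panel makes the whole
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    jsonlite,
    zip
Suggests:
    testthat (>= 3.0.0),
    mzR,
    readxl,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'formula-mass.R'
    'massql.R'
    'chromatogram.R'
    'methods-accessors.R'
    'msms.R'
    'mzSST-package.R'
    'mzml-io.R'
    'sst-batch.R'
    'report.R'
    'synthetic-data.R'
    'xlsx.R'
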