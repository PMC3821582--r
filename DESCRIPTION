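Package: isoshift
Title: Stable-Isotope Mass-Shift Filtering for Drug Metabolite Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects drug metabolites in liquid chromatography/mass
    spectrometry (LC-MS) data by comparing runs of a stable-isotope
    labeled and an un-labeled incubation. Features from the two runs are
    aligned and "twin ions" - ion pairs separated by the label mass that
    co-elute with similar intensity - are extracted under retention-time,
    mass and intensity-drift tolerances. Hits are characterized by
    exhaustive molecular-formula enumeration from accurate mass and by
    parent-relative mass defects, and compared against two conventional
    baselines: biotransformation-list matching and mass defect filtering.
    Includes LC-MS feature detection from centroided scans, reference-ion
    subtraction, a synthetic paired-run generator with ground truth, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
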