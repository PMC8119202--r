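Package: metaboflux
Title: Extracellular Flux, Stable-Isotope Tracing and Mitochondrial
    Morphometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative cellular-metabolism assays: extraction of
    mitochondrial and glycolysis stress-test parameters (basal/maximal
    respiration, proton leak, ATP-linked respiration, spare capacity,
    glycolysis, glycolytic capacity and reserve, glycoPER-based rates) from
    per-well OCR/ECAR plate exports; natural-abundance correction of
    mass-isotopologue distributions from [U-13C]-glucose tracing with
    citrate/pyruvate isotopologue surrogate ratios for pyruvate dehydrogenase
    and pyruvate carboxylase activity; a forward atom-mapped glycolysis/TCA
    label-propagation simulator with a Monte-Carlo oracle; mitochondrial
    morphometry (area, Feret diameter, shape classification) from traced
    outlines; and the replicate-aggregation and group-comparison statistics
    used in plate-based assay studies. Seeded synthetic-data generators for
    flux plates, labeling patterns and mitochondrial outlines provide ground
    truth for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    multcomp,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
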