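Package: flapsphenotyper
Title: Phenotyping Selfish Polysaccharide-Uptaking Bacteria from
    Fluorescence Images, Chromatograms and Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for identifying and quantifying "selfish"
    polysaccharide-uptaking bacteria in fluorescently labeled
    polysaccharide (FLAPS) incubation experiments. Provides multi-channel
    epifluorescence co-localization scoring (DAPI cell definition,
    multi-exposure FLAPS signal consolidation, FISH probe identification,
    autofluorescence exclusion), extracellular hydrolysis rates from
    gel-permeation chromatogram timecourses with killed-control
    correction, control-calibrated flow-cytometry gating of FLAPS-positive
    events, and a ground-truthed synthetic data generator for validating
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    graphics,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
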