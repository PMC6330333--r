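Package: sectionmap
Title: Serial-Section Brain Reconstruction and Retrograde-Label Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing whole brains from serial coronal
    fluorescence sections and mapping retrogradely labeled neurons onto
    anatomical regions. Implements maximum correlation thresholding (MCT)
    for tissue and soma segmentation, Moore-Neighbor boundary tracing,
    connected-component cell detection with shape filters, rigid
    rostro-caudal section alignment validated by boundary correlation,
    injection-site precision and region-distribution quantification, and a
    synthetic section-stack generator that provides complete ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
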