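Package: swcforge
Title: Validation, Repair and Conversion of Neural Morphology
    Reconstructions to Standard SWC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with skeletonized digital reconstructions of
    neuronal and glial morphology. Implements a reader, writer and validator
    for the seven-column SWC v1.0.0 text format, an ordered battery of
    specification checks with automatic error correction (invalid parents,
    malformed index and type fields, non-positive radii, out-of-order rows),
    detection and collapse of soma contour tracings via a curvature test, and
    converters from common text and XML reconstruction dialects (NeuronJ NDF,
    Neurolucida ASC, NEURON HOC, Eutectic NTS, KNOSSOS NML, NeuroML, extended
    SWC) into standardized SWC. A deterministic synthetic-morphology
    generator supports fixture-based testing of every pipeline stage, and a
    command-line interface mirrors the check-only and convert/standardize
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
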