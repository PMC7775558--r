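Package: synmorph
Title: Synaptic Ultrastructure Morphometry from Annotated Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative morphometry of presynaptic ultrastructure from
    coordinate annotations of electron micrographs. Parses the tab-separated
    per-image annotation text format exported by ImageJ/Fiji tracing macros,
    validates datasets, and computes sizes, counts and minimum distances of
    synaptic organelles relative to the plasma membrane, active zone and
    dense projection. Includes a blinded-randomization workflow with a
    persisted key, vesicle pool classification (docked, active zone,
    periactive, cytoplasmic), membrane-pit shape metrics (depth, base width,
    full-width-half-maximum diameter), binned distance distributions with
    normalized abundances, serial-section aggregation into per-synapse
    totals with 3D coordinate export, and a synthetic annotation generator
    with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
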