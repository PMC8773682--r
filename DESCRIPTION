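Package: netscan
Title: High-Content Screening Analysis of Neutrophil Extracellular Traps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-cell identification and quantification of neutrophil
    extracellular traps (NETs) from multi-channel fluorescence plate images.
    Segments Hoechst-stained nuclei, measures membrane-impermeable DNA dye
    (Sytox Green / propidium iodide) target area and intensity per cell,
    gates cells into NET-forming, other-death and live classes (with an
    Annexin V four-channel mode separating apoptosis from necrosis),
    aggregates per-well percent NETosis with plate-level statistics, links
    cells across time-lapse frames to classify death trajectories, and ships
    a synthetic ground-truth plate generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
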