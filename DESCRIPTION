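Package: cmdx
Title: Clinical Map Documents for Graphical Prostatectomy Pathology Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reader, writer and analysis engine for cMDX (clinical Map
    Document based on XML) packages: zip-based compound documents that
    combine a schematic prostate template (mask surfaces with per-slice
    volume factors, drawing tools, background image) with per-patient
    graphical pathology annotations (polygonal carcinoma foci with Gleason
    records, capsular invasion, surgical margins) and an encrypted clinical
    form. Implements pixel-count tumour volume estimation weighted by slice
    factors, multifocality classification by bounding-rectangle clustering,
    per-slice incidence, peripheral-zone localization, cohort cumulative
    frequency maps, a four-layer renderer with magic-wand flood fill, PDF
    report generation, and a synthetic specimen generator with recorded
    ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    zip,
    openssl,
    png,
    jpeg,
    tiff,
    grDevices,
    graphics,
    grid,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
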