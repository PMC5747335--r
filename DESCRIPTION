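Package: toolscribe
Title: Generate, Enrich and Audit Galaxy and CWL Tool Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bioinformatics software integrators who maintain
    workbench tool descriptions. Reads bio.tools-style registry entries
    (JSON following a BiotoolsSchema subset) and declarative command-line
    interface specifications, generates Galaxy tool XML and CWL
    CommandLineTool YAML skeletons, additively enriches existing
    descriptions with missing registry metadata (EDAM topic and operation
    annotations, citations, descriptions), matches description corpora to
    registry entries by DOI with a conservative one-to-one rule, and audits
    metadata completeness (help, description, citations, EDAM coverage and
    the DOI mapping funnel). Includes a seeded synthetic-corpus generator
    so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
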