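Package: hxmsr
Title: Read, Write, Validate and Convert Hydrogen-Deuterium Exchange
    Mass Spectrometry Data in the HXMS Format
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the HXMS text format for hydrogen-deuterium
    exchange mass spectrometry (HX/MS) data: a validated in-memory
    document model (experimental metadata, timepoint records with
    optional isotopic mass envelopes, and a dictionary of
    post-translational modifications), a bit-exact fixed-width
    reader and writer, envelope normalization, centroid and
    deuterium-uptake computation including zero-timepoint
    replicate-averaging, converters for several common HX/MS
    software export dialects plus a self-contained custom CSV
    layout, a synthetic-fixture generator, and a command-line
    interface for conversion, validation and inspection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
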