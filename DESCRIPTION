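Package: mrsnifti
Title: Read, Write, Validate and Create NIfTI-MRS Spectroscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implementation of the NIfTI-MRS data standard (version 0.6) for
    in-vivo magnetic resonance spectroscopy: up-to-7-dimensional complex
    time-domain data stored in NIfTI-2 files carrying a JSON-formatted header
    extension (NIfTI extension code 44). Provides creation, bit-exact reading
    and writing, conformance validation, metadata editing, anonymization of
    protected health information, conversion from text-based spectroscopy
    formats (LCModel RAW/H2O, jMRUI text, plain ASCII), chemical-shift axis
    and phasing utilities following the standard's frequency conventions, and
    a synthetic Lorentzian FID generator for fully reproducible example data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
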