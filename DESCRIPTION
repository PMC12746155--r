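Package: hitescreen
Title: Differential Metabolomics for High-Throughput Elicitor Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput elicitor screening (HiTES)
    of microbial secondary metabolomes by untargeted LC-MS. Provides
    control-subtracted differential induction maps over an elicitor library,
    elicitor ranking and hit calling, four-parameter-logistic dose-response
    fitting (IC50), bounded molecular-formula enumeration with RDBE and
    nitrogen-rule constraints, CH2 homolog-series detection, diagnostic-fragment
    compound-family grouping, acyl-chain carbon accounting, and stable-isotope
    (deuterium) labeling interpretation, together with seeded synthetic-data
    generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    mzR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
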