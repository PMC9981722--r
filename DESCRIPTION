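Package: phantomqa
Title: Automated Quality-Assurance Triage for Mammography Phantom Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated scoring and triage of ACR-156 style
    mammography accreditation phantom images. Provides a synthetic phantom
    renderer with exposure-dependent contrast and noise (mAs/kVp control),
    patch extraction and seeded dataset partitioning, a pair of per-shape
    scoring classifiers (a three-class scorer over visibility scores
    0/0.5/1 and a binary visible-vs-invisible scorer), ACR subtotal and
    pass/fail scoring, a threshold-controlled lenient/strict filtering
    algorithm that removes definite-pass and definite-fail images from the
    human reading queue, and evaluation statistics including exact
    Clopper-Pearson confidence intervals, F1 and Mann-Whitney AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
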