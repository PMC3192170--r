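Package: enrichMS
Title: Targeted MS/MS Quantification of Stable-Isotope Peptide Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the stable-isotope (deuterated-leucine) enrichment of
    in-vivo-labeled proteins from targeted LC-MS/MS product-ion data. Performs
    in-silico tryptic digestion, predicts labeled and unlabeled b/y fragment-ion
    m/z values, builds precursor target (inclusion) lists, extracts and
    integrates product-ion chromatographic peaks, computes percent enrichment as
    the ratio of summed labeled to unlabeled fragment peak areas, and provides
    the validation statistics used to qualify a peptide for enrichment
    measurement (replicate coefficient of variation, signal-linearity regression
    with an intercept test, and measured-versus-predicted enrichment
    regression). A synthetic targeted-run simulator with known ground truth
    makes every pipeline stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    mzR,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
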