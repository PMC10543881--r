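Package: fraglift
Title: Tumour Fraction Estimation from Cell-Free DNA Fragment-Length Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the tumour-derived fraction of cell-free DNA in a
    plasma sample from the shape of its fragment-length distribution.
    Extracts discrete Fourier features from quadratically detrended log
    fragment-length profiles (81-141 bp) and Daubechies-10 discrete wavelet
    features (81-336 bp), curates tumour-content training labels from
    panel-sequencing variant allele frequencies via Dirichlet-process
    clustering, fits a component-wise boosted beta regression with
    bootstrap-tuned stopping, performs complementary-pairs stability
    selection with a per-family error budget, and validates predictions on
    plasma dilution series. Includes a synthetic-data generator emulating
    nucleosomal fragment-length mixtures with 10-bp oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
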