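Package: phonoaccess
Title: Digitized Phono-Angiography of Hemodialysis Vascular Access Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and cohort analysis for auscultated bruits of
    hemodialysis arteriovenous fistulas and grafts. Implements a digitization
    pipeline (20-500 Hz bandpass, rectification, rolling-mean contour
    extraction, percentile normalization), peak/valley detection with
    interquartile-range outlier rejection, per-recording loudness features
    (mean peak, mean valley, peak-to-valley ratio) and the low-frequency
    spectral band percentage, plus group and paired pre/post-angioplasty
    comparisons. Includes a seeded synthetic bruit generator with
    cardiac-cycle envelope modulation and band-limited turbulence carriers,
    providing ground truth for validation in place of non-shareable patient
    audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
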