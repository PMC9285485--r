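Package: eegartefacts
Title: Automated Detection and Removal of Flat Lines and Large Amplitude
    Fluctuations in Neonatal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based detection and removal of the two predominant
    non-physiological artefacts in multichannel neonatal EEG recorded at
    term-equivalent age: flat line segments (lost electrode contact) and
    large amplitude fluctuations (movement, often with muscle activity).
    Flat lines are found from the thresholded absolute second difference
    with channel consensus and duration-dependent padding; large amplitude
    windows are found from the maximal absolute first difference, maximal
    absolute amplitude and the high-frequency power ratio, combined through
    four removal criteria and interval merging.  Includes EDF input/output,
    interval/mask algebra, sample-wise and multi-class evaluation metrics,
    and a seeded synthetic neonatal-EEG generator with ground-truth
    annotations for testing detector behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
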