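Package: ssvepuac
Title: Unsupervised Adaptive Template Classification for SSVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency recognition for steady-state visual evoked potential
    (SSVEP) brain-computer interfaces. Implements filter-bank canonical
    correlation analysis (FBCCA) and an unsupervised adaptive classifier
    (UAC) that builds per-frequency template banks online from its own
    estimated labels, superimposes templates onto incoming epochs, and
    integrates the template-augmented score with the static FBCCA score.
    Includes a phase-locked synthetic SSVEP epoch generator with controlled
    signal-to-noise ratio, readers for the two public SSVEP benchmark
    dataset layouts stored as MATLAB v5 files, and an evaluation harness
    replaying sequential-block online decoding protocols with accuracy and
    information-transfer-rate summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
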