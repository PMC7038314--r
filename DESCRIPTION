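Package: gaitseg
Title: Gait Segmentation and Spatiotemporal Indices from Plantar-Pressure Insoles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments human gait from multi-channel plantar-pressure insole
    recordings (eight anatomical sensor sites per foot). Detects initial
    contact and toe off with adaptive half-range thresholds on the heel and
    hallux signals, computes the center-of-pressure (CoP) trajectory and its
    instantaneous velocity, labels the four stance subphases (initial contact,
    forefoot contact, flat foot, forefoot push-off) from the anteroposterior
    CoP position, and reports spatiotemporal gait indices (CoP mean velocity,
    double-support time, cadence, stance/swing/double-support percentages).
    Includes a synthetic two-foot gait generator with ground-truth annotations
    so the whole pipeline is testable without hardware, plus CSV/JSON I/O and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
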