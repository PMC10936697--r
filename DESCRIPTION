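Package: regwave
Title: Rheoencephalography Pulse-Wave Morphology and Cerebral Autoregulation Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rheoencephalography (REG) and peripheral
    bioimpedance recordings: mains-interference suppression by running-average
    smoothing, artifact masking, beat segmentation, per-beat pulse-wave
    morphology (P1/P2/P3 amplitudes and latencies, anacrotic time, catacrotic
    shoulder detection, intracranial-compliance classification), the REGx/PRx
    moving-correlation autoregulation index from 10-second epoch averages in a
    5-minute window, and challenge analytics for 30-second breath-holding and
    head-down-tilt sessions. Includes a seeded synthetic-signal generator that
    produces multichannel sessions with known per-beat ground truth, a
    documented binary+metafile storage dialect, and EDF and CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
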