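Package: pupiltrend
Title: Slow Pupil-Diameter Trend Analysis for Event-Locked Pupillometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying slow, luminance-robust changes in pupil
    diameter ("pupil trends") around task events in continuous eye-tracking
    recordings. Provides blink detection with margin extension and linear
    interpolation, centered moving-average trend indices at 5-15 s windows,
    a conservative 14 s-span variant immune to event-locked phasic activity,
    and dyadic-scale trend indices from a shift-invariant Symlet-4
    multiresolution decomposition. Includes trial-exclusion bookkeeping,
    per-participant reaction-time splits (mean and quartile), accuracy and
    cue-condition contrasts, paired one-tailed tests with Benjamini-Hochberg
    false-discovery-rate control, and a deterministic synthetic-session
    generator (latent mean-reverting alertness state coupled to reaction
    times) for end-to-end validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
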