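Package: idoct
Title: Iterative Decomposition of Cognitive Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes trial-by-trial timecourses from computerised cognitive
    tasks into data-driven trial difficulty scales (unscaled D and
    ability-scaled DS), participant-specific cognitive ability (AS) and delay
    time (DT, the response-time component attributable to device latency,
    visuomotor processing and task-unspecific cognition). Estimation uses two
    fixed-point iterations that jointly calibrate trial difficulty from group
    performance and participant ability from the answer-time component of
    reaction time, handling speed-accuracy trade-offs and the sampling bias of
    adaptive (staircase) task designs. Includes a synthetic task-data
    generator with known ground truth for parameter-recovery studies,
    preprocessing filters for raw trial records, and a psychometric validation
    layer: sparse pairwise correlation, complete-linkage clustering,
    exploratory factor analysis with varimax rotation, Schmid-Leiman bifactor
    g-factor summaries and regression effect-size helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
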