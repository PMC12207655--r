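Package: gadflight
Title: Behavioural Analysis of Multi-Sensor Seabird Biologging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw multi-sensor biologger exports from pelagic
    seabirds into behavioural ethograms and activity budgets. Computes static
    and dynamic body acceleration metrics (VeDBA, VeSBA, pitch, roll,
    wingbeats) from 25 Hz tri-axial accelerometry, performs zero-offset
    correction and dive detection on 1 Hz time-depth-recorder streams,
    trains and evaluates random-forest behaviour classifiers with
    cross-validated tuning and recursive feature elimination, models diel
    activity as zero-inflated beta regressions on solar elevation, and
    segments central-place foraging trips from GPS tracks. Includes a
    synthetic logger simulator so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    pracma,
    ranger,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    caret,
    withr,
    optparse
Config/testthat/edition: 3
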