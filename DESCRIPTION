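Package: its311
Title: Interrupted Time-Series Evaluation of Sanitation Interventions
    from 311 Incident Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quasi-experimental evaluation of place-based
    public-health interventions (public restrooms and similar sanitation
    facilities) using municipal 311-style incident report streams.  Reads
    raw report exports, applies category and status-note inclusion rules,
    matches reports spatio-temporally to intervention sites via geodesic
    buffers, builds zero-filled weekly count panels around each
    intervention start date, and estimates pre/post changes two ways:
    permutation tests of the difference in mean weekly reports, and
    segmented negative-binomial (NB2) interrupted time-series regression
    with level-change and slope-change terms and sandwich (HC0) robust
    confidence intervals.  Includes a synthetic-data generator with the
    same statistical structure for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
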