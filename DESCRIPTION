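Package: idioscreen
Title: Idiographic Screenome Analysis via p-Technique Canonical Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for person-specific (idiographic) analysis of smartphone
    media use and mental health. Derives six media-use metrics from
    5-second-cadence screenshot-metadata event streams (sessionization,
    screen time, social screen time, session counts and durations, unique
    apps, app switches), scores fortnightly mental-health surveys (CES-D-10,
    STAI state, ASRS, positive affect) with clinical-risk flagging, and
    estimates within-person coupling between the two variable blocks by
    p-technique canonical correlation analysis solved by singular value
    decomposition, with significance assessed against a permutation null.
    Includes a synthetic screenome generator with an analytically known
    planted canonical correlation so every stage is testable without
    access to real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
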