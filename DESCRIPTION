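Package: rhythmkit
Title: Sleep and Circadian Rhythm Inference from Smartphone Screen Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers nightly sleep records (onset, wake time, midpoint of
    sleep, total sleep time) from passively collected smartphone event
    streams (screen-on, screen-off, notifications). Usage episodes are
    classified as proactive or reactive by the presence of a notification
    within a configurable lookback before screen-on; notification floods
    are excluded per app and day; sleep is detected as the maximal
    non-usage episode between proactive sessions inside a nightly window,
    with dummy-boundary labelling and resumption of original timestamps
    for episodes crossing the window. Cohort-level validation statistics
    (interval overlap ratio, paired indicator differences, midpoint-of-sleep
    correlations, social jetlag, sleep-efficiency proxy) compare device
    records against self-reported sleep diaries, and a synthetic event-log
    simulator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
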