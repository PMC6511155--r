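Package: t1dplan
Title: Rule-Based Care-Plan Construction and Real-Time Insulin Advice for
    Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic clinical decision-support library for type 1
    diabetes. Builds complete personalized care plans (insulin regimen via
    weight-based total daily dose and fixed or basal-bolus splits, diet via
    Harris-Benedict medical nutrition therapy, exercise and education
    sub-plans) from a coded patient profile and a configurable knowledge
    base, and gives real-time mealtime bolus advice (insulin sensitivity
    factor, insulin-to-carb ratio, exercise offsets) and multi-day glucose
    pattern management from sensor-style observations. Profiles, observation
    streams and plans are exchanged as FHIR-style JSON bundles; a synthetic
    data generator produces reproducible patient cohorts and glucose logs
    with injectable out-of-range patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
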