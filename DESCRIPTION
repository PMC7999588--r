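Package: fallwatch
Title: Fall-Risk Screening from Depth-Sensor Home Monitoring
Version: 0.1.0
Authors@R: person("fallwatch", "maintainers", email = "fallwatch@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for ambient fall-risk screening
    of older adults from a single room-mounted depth sensor. Generates
    synthetic monitored cohorts (daily activity schedules, 3D body-centroid
    trajectories, optional rendered depth frames with full ground truth),
    extracts fifteen behavioral parameters (gait spatio-temporal measures from
    vertical centroid oscillation, sit-stand transition times and speeds,
    activity-time budgets), assigns reference fall-risk labels from Tinetti
    and Timed Up and Go scores, benchmarks all one- and two-parameter
    combinations across nine classifiers under leave-one-subject-out
    cross-validation, and runs Holm-corrected two-group comparisons with
    bootstrap confidence intervals on relative differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    quadprog,
    stats,
    truncnorm,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
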