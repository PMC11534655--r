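Package: crankforce
Title: Neuromuscular Profiling from Isometric Mid-Thigh Pull Force and
    Sprint-Cycling Crank Torque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing neuromuscular performance tests used in
    sprint cycling research.  Extracts onset, peak force and rate of force
    development (RFD) metrics from raw isometric mid-thigh pull (IMTP)
    force-time trials; segments pedal downstrokes from crank-torque traces
    and derives rate of torque development (RTD), observed session peaks
    and torque-cadence / power-cadence profile parameters (T0, RPMmax,
    Pmax, RPMopt); and computes pre/post training-response statistics
    (percent change, bias-corrected Hedge's g with confidence intervals and
    magnitude labels, Pearson correlations on the Hopkins-modified Cohen
    scale).  A synthetic-data generator with known ground truth makes every
    stage of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
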