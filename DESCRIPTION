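Package: voltmapr
Title: Active-Learning Planning for Cardiac Voltage Mapping with Gaussian
    Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequential next-best-point planning for electroanatomical
    voltage mapping. A Gaussian-process surrogate predicts the voltage
    field over a candidate domain (2D grid or triangulated surface mesh)
    and the next mapping point maximizes the posterior entropy of the
    prediction, optionally per unit catheter travel distance. The kernel
    hyperparameter is either fixed to a prior learned from expert
    demonstration sequences (pure exploitation) or tracked online by a
    regularized particle filter with an Epanechnikov resample-move step
    (implicit exploration). Includes a greedy geometry-coverage baseline
    planner, Gaussian-mixture synthetic fields, SSIM and mean-L1
    evaluation, and a reproducible 2D grid benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
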