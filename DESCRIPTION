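Package: ovichoice
Title: Statistical Analysis of Two-Choice and Gradient Oviposition Playback Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing insect oviposition-choice experiments with
    acoustic playback: simulation of two-choice arena-night cluster counts,
    gradient-arena egg positions and side-switching moth trajectories; Poisson
    mixed-model inference on cluster counts; a Bayesian posterior for the
    per-cluster choice probability; a mirror-shuffle permutation null with the
    two-sample Kolmogorov-Smirnov test for spatial egg distributions;
    trajectory side-occupancy and crossing analysis; and Pearson chi-square
    validation of a 2x2 response table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
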