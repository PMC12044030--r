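Package: wmreselect
Title: Reselection of Visual and Motor Working-Memory Content After
    Interruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for EEG, eye-tracking, and continuous-report
    behavioral data from retro-cue working-memory experiments with an
    embedded interrupting task. Implements Morlet time-frequency
    decomposition with a fixed-duration analysis window, hemispheric
    lateralization indices for posterior alpha (visual) and central beta
    (motor) activity, gaze towardness, circular mixture-model decomposition
    of orientation-report errors, moving-window response-bias curves,
    cluster-based sign-flip permutation inference, generalized extreme
    studentized deviate trial rejection, and normalized cross-correlation
    lag analysis. A synthetic-data generator reproduces the task's
    statistical structure so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
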