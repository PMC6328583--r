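Package: myoslice
Title: Digital Twin and Analysis Chain for Force-Monitored Myocardial Slice Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a human myocardial tissue slice cultured under
    physiological preload in an instrumented chamber (elastic spring load,
    magnetic displacement sensing, charge-balanced field stimulation) and
    implements the full measurement chain used with such devices: twitch
    detection and contractility summaries from raw magnetic-flux traces,
    paired-pulse refractory-period determination, Hill dose-response fitting
    for pro-arrhythmic drug effects, wall-stress and length-tension
    biomechanics, Fourier-based sarcomere-length and membrane-distance
    morphometry on confocal image stacks, and linear time-trend analysis of
    gene-expression log2 ratios over weeks of culture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    minpack.lm,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
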