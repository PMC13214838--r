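Package: circalux
Title: Simulating Full-Day Light Exposure Effects on Sleep and Circadian Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Couples a light-driven van der Pol limit-cycle model of the human
    circadian pacemaker (with a photoreceptor saturation process) to a
    two-process sleep homeostat with circadian-modulated thresholds, and runs
    it over constructed laboratory light schedules: an evening eBook versus
    paper-book reading protocol, bright-light equilibration schedules, and
    baseline-plus-pulse days. Provides parameter-grid sweeps with physiological
    validity filtering, phase-marker extraction (core body temperature minimum
    and dim light melatonin onset), sleep onset latency and phase-shift
    analyses, actograms, and circadian-amplitude maps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
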