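Package: chronoloh
Title: Circadian Rhythmicity, Apc Copy-Number Loss and Clock-Wnt Survival
    Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking circadian-clock disruption to Apc loss of
    heterozygosity and patient outcome. Implements detrending, JTK_CYCLE
    rhythmicity testing with an exact Kendall-S null, FFT-NLLS damped-cosine
    period and amplitude estimation and strict period gating for organoid
    bioluminescence recordings; Poisson-corrected digital-PCR copy-number
    estimation; read-depth loss-of-heterozygosity segment detection with an
    empirical-Bayes moderated t filter; and a clock-Wnt covariance survival
    stratification built on biweight midcorrelation networks, principal
    component contributions, Kaplan-Meier curves and the log-rank test.
    Seeded synthetic-data generators with planted ground truth make every
    stage testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    survival,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
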