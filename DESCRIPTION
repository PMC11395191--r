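Package: cardiophen
Title: Cardiac Phenotyping of Mouse ECG, Pressure-Volume, Calcium, and Echo Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end phenotyping toolkit for murine cardiac physiology
    studies comparing two genotypes. Implements QT-interval detection on
    averaged Lead-I ECG cycles via the J-wave anchored derivative-zero
    T-end rule and windowed QT-variation (coefficient of variation);
    segmentation of left-ventricular pressure-volume traces with linear
    ESPVR/EDPVR fitting across preload-reduction cycles, including an
    incremental negative-slope exclusion rule for perfusion-compromised
    cycles; background-subtracted Fura-2 F340/F380 ratio analysis with
    ensemble averaging of paced transients and kinetic metrics (baseline,
    peak amplitude, time to peak, time to 90% baseline, tau); Teichholz
    echocardiographic derivations (FS, ESV, EDV, SV, EF); and the group
    statistics used in such studies (a-priori 2-SD outlier exclusion,
    pooled Student's t, hierarchical nested t-tests, Livak 2^-ddCt with
    dual reference genes). Ships seeded synthetic-signal generators with
    analytic ground truth (beat-template ECG, time-varying-elastance PV
    loops with occlusion ramps, ratiometric photometry, hierarchical
    cohorts) so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
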