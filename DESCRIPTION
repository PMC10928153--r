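Package: wktau
Title: Diastolic Pressure Decay Time Constant from Central Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the central diastolic pressure decay time
    constant (tau) under the two-element Windkessel model. Provides an exact
    periodic Windkessel solver driven by parametric ejection flow waves, a
    seeded virtual-population generator emulating a published in silico
    cohort, pressure-waveform feature extraction (beat averaging,
    Savitzky-Golay smoothing, diastolic/mean calibration, mean-pressure
    estimation formulas), three tau estimators (the R*C reference, a
    mono-exponential diastolic decay fit, and the closed-form product of
    heart period and the mean-to-pulse-pressure ratio scaled by a fitted
    coefficient), the pulse pressure method for total arterial compliance,
    origin-constrained coefficient fitting with subgroup and sensitivity
    analyses, and a method-agreement battery (Pearson r, intraclass
    correlation, normalized RMSE, Bland-Altman limits of agreement, and
    Wald-tested least-squares regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
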