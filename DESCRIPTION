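Package: lipidpanelr
Title: Lipid Panel Discovery and Cross-Cohort Validation for
    Direct-Infusion Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting clinical lipoprotein concentrations
    (triglyceride, HDL-, LDL- and total cholesterol) from direct-infusion
    mass-spectrometry lipid profiles. Provides ppm-window spectral matching
    of centroided peak lists against a lipid target library, a four-step
    quality-control filter chain (mass deviation, blank ratio, missingness,
    QC dilution-series linearity) followed by total-signal normalisation and
    per-cohort mean centering, random-forest panel discovery with iterative
    forward panel growth, translation and re-training of panels in a second
    cohort (e.g. dried blood spots), per-lipid generalised linear models
    with Bonferroni control, and stratification of subjects by clinical
    cut-offs or quartiles with permutation chance baselines. Includes a
    synthetic-data generator producing paired cohorts (spectra, blanks, a
    three-level QC dilution series and clinical tables) with planted
    lipid-lipoprotein associations so the whole pipeline is testable
    without access to cohort data.
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
    randomForest,
    rlang,
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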