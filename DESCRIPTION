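Package: wmfcs
Title: White-Matter Functional Connectivity Strength Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying white-matter function in resting-state BOLD
    fMRI through region-wise functional connectivity strength (FCS). Provides
    a synthetic cohort generator with a prescribed within/between-tissue
    correlation structure, motion quality control (Power's framewise
    displacement, Euler-number modified Z-scores), frame-level cleaning
    (volume dropping, motion censoring with interpolation, Friston 24-parameter
    nuisance regression, discrete-cosine high-pass filtering), combined
    gray/white-matter parcellation bookkeeping and time-series extraction,
    Fisher-z connectivity matrices with WW-FCS and GW-FCS summaries,
    covariate-adjusted group inference with Benjamini-Hochberg false discovery
    rate control, radiation-dose partial correlations, and post hoc power
    analysis. Everything is table-first: functions take and return tibbles so
    a full analysis chains with the pipe.
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
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
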