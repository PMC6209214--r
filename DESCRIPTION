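Package: bspquant
Title: Quantifying EEG Burst Suppression in Pharmacologically Induced Coma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the amount of EEG suppression achieved
    during pharmacologically induced coma, as used in the management of
    refractory status epilepticus. Implements burst/suppression segmentation
    of multichannel scalp EEG (average montage, band-pass filtering,
    amplitude-based artifact rejection, per-channel binarization and
    cross-channel voting), state-space estimation of the burst suppression
    probability (BSP) with credible intervals from binomial epoch counts,
    compliance metrics against a clinical reference band (time above /
    within / below band, accurate and reliable control labels, Beta-binomial
    group posteriors with Monte Carlo group comparison), and analysis of BSP
    drift and between-patient variability during constant anesthetic
    infusion rates. A pharmacokinetic/pharmacodynamic simulator generates
    synthetic cohorts (EEG, medication records, intent periods) with known
    ground truth for validation.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
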