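Package: gistcea
Title: Cost-Utility Analysis of Adjuvant Imatinib After Resection of
    High-Risk GIST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model comparing six treatment
    strategies for patients with a high risk of recurrence after complete
    resection of a gastrointestinal stromal tumour (GIST) in Thailand:
    no adjuvant therapy versus one or three years of adjuvant imatinib,
    crossed with the drug sequence given on recurrence and progression
    (imatinib, sunitinib, best supportive care). The package houses every
    model input with its uncertainty distribution (Beta, Gamma, Lognormal
    fitted by method of moments), derives the three-year treatment effect
    by Bucher indirect comparison, runs the cohort model over a lifetime
    horizon with 3% annual discounting, and computes incremental
    cost-effectiveness ratios, the efficiency frontier with extended
    dominance, one-way (tornado) and probabilistic sensitivity analyses,
    cost-effectiveness acceptability curves, and the imatinib price at
    which adjuvant treatment becomes cost-effective at the Thai
    willingness-to-pay threshold of 160,000 THB per QALY.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
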