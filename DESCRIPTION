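Package: cervscreen
Title: Evaluation Statistics for AI-Assisted Cervical Cytology Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating an AI-assisted cervical cytology arm against
    manual cytology reading inside a population-based screening programme.
    Implements rank-weighted aggregation of per-cell prediction scores into a
    slide-level score with adequacy checking; the dual-arm partial-verification
    screening protocol (full review of AI-abnormal slides plus a random sample
    of AI-normal slides, LSIL+ referral by either arm); inter-method agreement
    statistics on the paired 5x5 Bethesda grade table (agreement rates, Cohen's
    and linear-weighted kappa, one-vs-rest kappas, McNemar's test); diagnostic
    accuracy under the concordant-normal augmentation design (per-grade CIN2+
    detection rates with exact intervals, Cochran-Armitage trend, sensitivity
    and specificity at the LSIL+ threshold, paired-arm odds ratios via a
    logistic generalized estimating equation, cluster-robust prevalence); and a
    seeded age-structured cohort simulator with correlated graded readers for
    validating the whole pipeline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
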