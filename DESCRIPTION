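Package: matchedHMM
Title: Personalized Matched-Pair Differential Expression with a
    Three-State Gaussian Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalized differential expression analysis of patient-matched
    tumor sample pairs (e.g. intracranial versus extracranial metastases).
    Per-pair log2-ratio expression profiles ordered along chromosomes are
    segmented by a three-state Gaussian hidden Markov model ('-', '=', '+')
    trained with a Bayesian (MAP) Baum-Welch algorithm and decoded by state
    posteriors. Downstream stages: chromosome-wise autocorrelation with a
    permutation null, Fisher-exact pathway enrichment with FDR control,
    per-patient majority-vote consensus and cross-patient gene ranking,
    pair-overlap statistics, and a quartile Kaplan-Meier survival screen.
    A synthetic-cohort generator reproduces the statistical structure the
    pipeline assumes so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    limma,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
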