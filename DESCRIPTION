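Package: srcsig
Title: Transformation-Regulated Gene Discovery and an Aggressive Tumor
    Signature from v-Src Microarray Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for calling transformation-dependent genes
    from multi-condition oligonucleotide microarray experiments
    (median scaling, invariant-set normalization, a perfect-match-only
    model-based expression index, two-fold/ANOVA calling with
    permutation-based false discovery rates, and temperature-confound
    filtering), for deriving an aggressive tumor gene signature from
    training tumor cohorts by Pearson-distance clustering and
    poor-prognosis-cluster enrichment, and for evaluating signatures
    against survival outcomes with an upper-quartile mean-centered score,
    Kaplan-Meier curves, restricted mean survival and the log-rank test.
    Includes seeded generators for probe-level microarray experiments and
    survival-annotated tumor cohorts with known planted truth, so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
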