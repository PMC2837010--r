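# srcsig

Discovery of transformation-regulated genes from multi-condition
microarray experiments, derivation of an aggressive tumor gene signature
from training tumor cohorts, and evaluation of that signature against
survival outcomes.

## The problem

The v-Src oncoprotein, the transforming tyrosine kinase of the Rous
sarcoma virus, rewires transcription when it transforms primary cells.
Comparing cells infected with transforming, transformation-deficient and
temperature-sensitive (ts) virus mutants separates genes regulated by
transformation itself from those responding to infection or culture
temperature. The genes regulated across multiple cell systems — the
**common set of v-Src-regulated (CSR) genes** — can then be used to
interrogate human tumor cohorts: clustering training tumors on the
up-regulated CSR orthologs exposes a poor-prognosis subgroup, and the
genes over-expressed in that subgroup across independent training cohorts
form an **aggressive tumor gene signature** whose high expression marks
patients with reduced disease- or metastasis-free survival.

`srcsig` implements this full pipeline for computational biologists who
want to rerun, probe or extend the analysis:

* **Preprocessing** — median scaling across experiments, rank-invariant-set
  normalization within each experimental group, and a perfect-match-only
  model-based expression index, `PM(i,j) = φ(i)·θ(j) + ε`, fit by
  alternating least squares with `mean(φ) = 1`.
* **Differential calling** — two-fold rule on log2 expression plus an
  unpaired t-test (pairwise regimes, p ≤ 0.05) or one-way ANOVA with a
  transformation-specific ≥2-fold contrast (three-virus regime, p ≤ 0.01);
  permutation-based FDR; removal of temperature-confounded genes; and the
  closing set algebra (TR, common, ts-only, CSR sets).
* **Signature derivation** — hierarchical clustering of training tumors
  (distance `1 − Pearson r`, average linkage, k = 4), poor-cluster
  selection by restricted mean survival, one-tailed candidate genes
  (p < 0.05), and the cross-training intersection.
* **Survival evaluation** — per-tumor score = mean gene-wise mean-centered
  signature expression; upper-quartile split; Kaplan-Meier curves,
  restricted means and the log-rank test (via the `survival` package).
* **Synthetic data** — seeded generators for probe-level experiments and
  survival-annotated tumor cohorts with planted truth, so the whole
  pipeline is testable without external data. The published 42-gene
  signature ships as a fixture (`load_aggressive_signature()`).

## Worked example

End-to-end discovery on a synthetic bundle (three experiments sharing a
planted 200-gene program; default conditions):

```r
library(srcsig)
run <- run_discovery(pipeline_config(n_permutations = 200, seed = 1))
print(run)
#> discovery_run
#>           set   n up down
#> 1          TR 184 91   93
#> 2      CEF_ts 189 92   97
#> 3      CNR_ts 191 95   96
#> 4 common_all3 181 89   92
#> 5     ts_only   5  2    3
#> 6         CSR 186 91   95
#> 7   TR_CEF_ts 181 89   92
#>   planted-program sensitivity: 0.93; realized FDP: 0.000
```

The CSR set recovers 93% of the 200 planted genes with no false
discoveries; `run$fdr` holds the per-regime permutation FDR estimates.

Signature derivation and evaluation on two training cohorts and one test
cohort sharing a planted 30-gene aggressive program (hazard ratio 3):

```r
study <- simulate_signature_study(seed = 2)
sig <- run_signature(study$csr_up, study$train_a, study$train_b,
                     study$test, pipeline_config())
print(sig$evaluations$test)
#> signature_evaluation (disease-free, years)
#>   groups: high = 50, rest = 150
#>   restricted mean survival (tau = 57): high = 3.76, rest = 12.2 years
#>   log-rank: chi-square = 48.973, p = 2.59e-12
```

The derived signature contains all 30 planted genes (training concordance
0.94), and the top quartile of test-cohort tumors by signature score has a
restricted mean disease-free survival of 3.8 years versus 12.2 years for
the rest.

The methods vignette (`vignettes/vsrc-signature-methods.Rmd`) documents
the models, parameter defaults and design decisions.

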