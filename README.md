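# txclust

Unsupervised phenotype discovery for kidney-transplant registry cohorts.

Recipients of high-KDPI deceased-donor kidneys (Kidney Donor Profile Index
≥ 85%, the top predicted-risk stratum) are clinically heterogeneous.
`txclust` clusters such recipients by their pattern of mixed-type recipient,
donor and transplant characteristics and asks which groups exist, what
distinguishes them, and whether their post-transplant outcomes differ. The
package covers the whole workflow:

* **Synthetic registry** — `generate_cohort()` simulates cohorts with a
  planted six-phenotype structure (~22 mixed-type variables, UNOS regions,
  cluster-specific outcomes, MCAR missingness), so the pipeline is testable
  without access to a real registry extract.
* **Preprocessing** — `apply_inclusion()` (KDPI ≥ 85, no multi-organ
  transplants, year window), `impute_chained()` (chained-equation
  imputation), `gower_distance()` (Gower dissimilarity for mixed types).
* **Consensus clustering** — `run_consensus()` subsamples 80% of subjects
  100 times and re-clusters (PAM by default) at every k in 2..10. The
  consensus value of a subject pair is its co-clustering rate among
  co-sampled iterations. `compute_diagnostics()` derives the consensus CDF,
  delta area, PAC (proportion of ambiguously clustered pairs, the fraction
  of pairs with consensus strictly inside (0.1, 0.9)) and within-cluster
  consensus scores; `select_k()` picks k (highest mean cluster consensus by
  default; PAC-minimizing and rank-sum composite rules included).
* **Characterization** — `smd_profile()` computes standardized mean
  differences of each cluster versus the overall cohort,
  SMD = (m_a − m_b)/√((s_a² + s_b²)/2) for continuous summaries and
  (p_a − p_b)/√((p_a(1−p_a) + p_b(1−p_b))/2) per categorical level, flagging
  |SMD| > 0.3 as key features; `region_proportions()` tabulates cluster mix
  by UNOS region.
* **Outcomes** — `outcome_summary()` builds the registry-style outcome
  table: Kaplan–Meier survival at 1 and 5 years with log-rank tests for
  patient death, death-censored graft failure and all-cause graft failure,
  and chi-squared comparisons for primary non-function, delayed graft
  function and 1-year acute rejection.

## Worked example

```r
library(txclust)

# a 600-recipient synthetic cohort with six planted phenotypes
syn    <- generate_cohort(simulation_config(n_subjects = 600, seed = 1))
cohort <- inject_missingness(syn$cohort, rate = 0.05, seed = 2)
cohort <- impute_chained(cohort, n_cycles = 5, seed = 3)

d    <- gower_distance(cohort)
run  <- run_consensus(d, consensus_config(seed = 4))   # k = 2..10, 100 x 80%
diag <- compute_diagnostics(run)
diag
#> <k_diagnostics>
#>   k    pac cdf_area delta_area mean_cluster_consensus
#>   2 0.4752   0.3453     0.3453                 0.8782
#>   3 0.3371   0.5792     0.6771                 0.8684
#>   4 0.2499   0.7027     0.2133                 0.8703
#>   5 0.0048   0.7795     0.1093                 0.9958
#>   6 0.0034   0.8342     0.0702                 0.9978
#>   7 0.0510   0.8487     0.0174                 0.9533
#>   8 0.0526   0.8637     0.0177                 0.9549
#>   9 0.0462   0.8782     0.0167                 0.9423
#>  10 0.0411   0.8910     0.0146                 0.9348

(k <- select_k(diag))
#> [1] 6
assign6 <- run$runs[["6"]]$assignment
adjusted_rand_index(assign6$labels, syn$true_labels)
#> [1] 0.9715

smd_profile(cohort, assign6)   # key features per recovered cluster (excerpt)
#> <smd_profiles> cutoff |SMD| > 0.3
#>   cluster 3 (n=98): pra (2.79), retransplant=yes (2.61), esrd_cause=other (1.9),
#>                     serum_albumin (-1.49), dialysis_duration=>3yr (1.3), ...
#>   cluster 5 (n=93): donor_age (-3.24), ecd_donor=yes (-2.6), dual_kidney=yes (2.1), ...
#>   ...

outcome_summary(syn$outcomes, assign6)$tests
#>                  outcome        test statistic df      p_value p_bonferroni
#> 1   primary_non_function chi-squared  5.218785  5 3.897672e-01 1.000000e+00
#> 2 delayed_graft_function chi-squared 13.492304  5 1.917722e-02 1.150633e-01
#> 3          rejection_1yr chi-squared  8.154905  5 1.479026e-01 8.874155e-01
#> 4         death_survival    log-rank 59.549184  5 1.506196e-11 9.037174e-11
#> 5      dc_graft_survival    log-rank  3.277527  5 6.572839e-01 1.000000e+00
#> 6         graft_survival    log-rank 35.053694  5 1.467978e-06 8.807869e-06
```

Reading the diagnostics the way a consensus-clustering analyst would: PAC
bottoms out at the planted k = 6 (0.34% of pairs ambiguous, versus 25-48%
at k = 2..4), the mean within-cluster consensus peaks at k = 6 (0.998), and
the delta-area gain collapses beyond 6 — so `select_k()` returns 6, and the
recovered partition matches the planted labels almost perfectly (adjusted
Rand index 0.97). The SMD profiles then read off each phenotype's
signature: the retransplant cluster surfaces high panel-reactive antibody
and retransplant status, the pediatric-donor cluster surfaces donor age,
non-ECD status and dual transplants. The planted per-cluster death hazards
(solved from published 5-year survival) make the log-rank comparison for
patient survival decisive, while delayed graft function differs more
weakly, mirroring a registry-style outcome table.

## Vignette

`vignettes/phenotype-discovery.Rmd` documents the model and conventions:
the consensus/PAC machinery, the Gower distance and imputation choices, how
the synthetic benchmark is designed (and what it deliberately does not
emulate), outcome-analysis conventions, and known limitations.
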