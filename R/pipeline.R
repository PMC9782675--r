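#' @keywords internal
"_PACKAGE"

#' End-to-end phenotype discovery pipeline
#'
#' Convenience wrapper chaining the full analysis: inclusion filtering,
#' chained-equation imputation, Gower dissimilarity, consensus clustering
#' over the k grid, stability diagnostics and k selection, SMD cluster
#' characterization, and cluster-wise outcome comparison (when outcomes are
#' supplied).
#'
#' @param cohort A [cohort_table()] (possibly with missing cells).
#' @param outcomes Optional outcome data.frame aligned to the cohort rows
#'   (see [outcome_summary()]); filtered alongside the cohort.
#' @param criteria [inclusion_criteria()], or `NULL` to skip filtering.
#' @param consensus [consensus_config()].
#' @param characterization [characterization_config()].
#' @param rule k-selection rule passed to [select_k()].
#' @param impute_cycles,impute_seed Passed to [impute_chained()].
#' @return List with `cohort` (filtered, completed), `distance`, `run`,
#'   `diagnostics`, `k`, `assignment`, `profiles`, and (if outcomes given)
#'   `outcomes` (the filtered table) and `outcome_summary`.
#' @export
phenotype_pipeline <- function(cohort, outcomes = NULL,
                               criteria = inclusion_criteria(),
                               consensus = consensus_config(),
                               characterization = characterization_config(),
                               rule = "mean_consensus",
                               impute_cycles = 10, impute_seed = 1L) {
  if (!is.null(criteria)) {
    before <- cohort$subject_id
    cohort <- apply_inclusion(cohort, criteria)
    if (!is.null(outcomes)) outcomes <- outcomes[before %in% cohort$subject_id, , drop = FALSE]
  }
  cohort <- impute_chained(cohort, n_cycles = impute_cycles, seed = impute_seed)
  distance <- gower_distance(cohort)
  run <- run_consensus(distance, consensus)
  diagnostics <- compute_diagnostics(run)
  k <- select_k(diagnostics, rule = rule)
  assignment <- run$runs[[as.character(k)]]$assignment
  profiles <- smd_profile(cohort, assignment, characterization)
  out <- list(cohort = cohort, distance = distance, run = run,
              diagnostics = diagnostics, k = as.integer(k),
              assignment = assignment, profiles = profiles)
  if (!is.null(outcomes)) {
    out$outcomes <- outcomes
    out$outcome_summary <- outcome_summary(outcomes, assignment)
  }
  out
}
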