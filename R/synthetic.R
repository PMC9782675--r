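#' Simulation configuration for a synthetic transplant registry
#'
#' Bundles everything the generator needs: cohort size, the planted cluster
#' structure (weights + per-cluster variable parameters), the missingness
#' rate, per-cluster outcome parameters, administrative censoring, and the
#' master seed.
#'
#' @param n_subjects Number of recipients to simulate.
#' @param n_clusters_true Number of planted clusters.
#' @param cluster_weights Cluster membership probabilities; must have length
#'   `n_clusters_true` and sum to 1 (within 1e-9).
#' @param variable_specs List of [variable_spec()] objects; per-cluster
#'   parameters are recycled to `n_clusters_true`.
#' @param missing_rate Per-cell missingness probability in `[0, 1)` applied by
#'   [inject_missingness()]; default 0.05, the upper bound typical of registry
#'   extracts.
#' @param outcome_specs Per-cluster outcome parameters, see
#'   [default_outcome_specs()].
#' @param admin_censor_time Administrative censoring horizon in years.
#' @param region_probs Clusters x 11 matrix of UNOS-region membership
#'   probabilities (rows sum to 1); defaults to [default_region_probs()] for
#'   six clusters and a uniform mix otherwise.
#' @param admin_vars Generated columns excluded from clustering distance
#'   (inclusion bookkeeping).
#' @param seed Master seed; all generator randomness derives from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 600,
                              n_clusters_true = 6,
                              cluster_weights = NULL,
                              variable_specs = default_registry_specs(),
                              missing_rate = 0.05,
                              outcome_specs = default_outcome_specs(),
                              admin_censor_time = 10,
                              region_probs = NULL,
                              admin_vars = c("multi_organ", "transplant_year"),
                              seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("invalid config field 'n_subjects': must be a positive count", call. = FALSE)
  }
  if (!is.numeric(n_clusters_true) || n_clusters_true < 1) {
    stop("invalid config field 'n_clusters_true': must be a positive count", call. = FALSE)
  }
  if (is.null(cluster_weights)) cluster_weights <- rep(1 / n_clusters_true, n_clusters_true)
  if (length(cluster_weights) != n_clusters_true) {
    stop("invalid config field 'cluster_weights': length must equal n_clusters_true", call. = FALSE)
  }
  if (abs(sum(cluster_weights) - 1) > 1e-9 || any(cluster_weights < 0)) {
    stop("invalid config field 'cluster_weights': must be probabilities summing to 1", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("invalid config field 'missing_rate': must lie in [0, 1)", call. = FALSE)
  }
  if (admin_censor_time <= 0) {
    stop("invalid config field 'admin_censor_time': must be positive", call. = FALSE)
  }
  if (is.null(region_probs)) {
    region_probs <- if (n_clusters_true == 6) default_region_probs()
                    else matrix(1 / 11, n_clusters_true, 11)
  }
  region_probs <- rbind(region_probs)
  if (nrow(region_probs) == 1) region_probs <- region_probs[rep(1, n_clusters_true), , drop = FALSE]
  if (nrow(region_probs) != n_clusters_true || ncol(region_probs) != 11 ||
      any(abs(rowSums(region_probs) - 1) > 1e-9)) {
    stop("invalid config field 'region_probs': clusters x 11 with rows summing to 1", call. = FALSE)
  }
  validate_outcome_specs(outcome_specs, n_clusters_true)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_clusters_true = as.integer(n_clusters_true),
         cluster_weights = cluster_weights,
         variable_specs = variable_specs,
         missing_rate = missing_rate,
         outcome_specs = outcome_specs,
         admin_censor_time = admin_censor_time,
         region_probs = region_probs,
         admin_vars = admin_vars,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

validate_outcome_specs <- function(specs, k) {
  rates <- c("death_rate", "graft_failure_rate")
  probs <- c("pnf_prob", "dgf_prob", "rejection_prob")
  for (f in c(rates, probs)) {
    v <- specs[[f]]
    if (is.null(v)) stop("outcome_specs missing field '", f, "'", call. = FALSE)
    if (length(v) == 1) v <- rep(v, k)
    if (length(v) != k) stop("outcome_specs field '", f, "' must have one value per cluster", call. = FALSE)
    if (f %in% rates && any(v <= 0)) stop("outcome_specs field '", f, "' must be positive", call. = FALSE)
    if (f %in% probs && (any(v < 0) || any(v > 1))) {
      stop("outcome_specs field '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(specs)
}

norm_rows <- function(m) sweep(m, 1, rowSums(m), "/")

#' Default synthetic variable roster
#'
#' About twenty mixed-type recipient/donor/transplant variables for six
#' planted phenotypes of a high-KDPI deceased-donor transplant cohort: a
#' young Black hypertensive long-dialysis-vintage cluster, an elderly White
#' preemptive/short-vintage cluster, a sensitized retransplant cluster, a
#' dual-transplant pediatric-donor cluster, a low-HLA-mismatch cluster, and a
#' diabetic cluster. Two administrative columns (`multi_organ`,
#' `transplant_year`) support inclusion filtering.
#'
#' Two parameter sets are provided. `"separated"` (the default) encodes each
#' phenotype as a near-deterministic signature — dominant category
#' probabilities around 0.9 and small within-cluster SDs — with the
#' signatures balanced so every pair of clusters differs clearly on several
#' variables; this is the planted-structure benchmark the clustering
#' pipeline is validated against. `"realistic"` uses per-cluster marginal
#' summaries typical of an actual high-KDPI registry cohort; its clusters
#' overlap heavily, which is faithful to registry data but makes full
#' recovery intrinsically hard.
#'
#' @param separation `"separated"` (benchmark signatures, default) or
#'   `"realistic"` (registry-style overlapping marginals).
#' @return List of [variable_spec()] objects for six clusters.
#' @export
default_registry_specs <- function(separation = c("separated", "realistic")) {
  separation <- match.arg(separation)
  if (separation == "separated") return(separated_registry_specs())
  list(
    variable_spec("recipient_age", "continuous",
                  mean = c(57.2, 68.0, 57.3, 51.7, 63.3, 63.3),
                  sd   = c(9.9, 6.9, 11.0, 13.7, 8.7, 7.2)),
    variable_spec("recipient_male", "binary",
                  prob = c(0.611, 0.642, 0.625, 0.508, 0.559, 0.695)),
    variable_spec("recipient_race", "categorical",
                  levels = c("White", "Black", "Hispanic", "Other"),
                  prob = norm_rows(rbind(
                    c(0.103, 0.654, 0.155, 0.088),
                    c(0.727, 0.094, 0.087, 0.092),
                    c(0.456, 0.364, 0.090, 0.090),
                    c(0.253, 0.245, 0.212, 0.289),
                    c(0.477, 0.243, 0.199, 0.081),
                    c(0.270, 0.363, 0.242, 0.125)))),
    variable_spec("bmi", "continuous",
                  mean = c(28.6, 27.3, 27.4, 24.8, 28.7, 29.6),
                  sd   = c(5.3, 4.7, 5.4, 4.1, 5.0, 4.8)),
    variable_spec("retransplant", "binary",
                  prob = c(0, 0, 1, 0.021, 0, 0)),
    variable_spec("dialysis_duration", "ordinal",
                  levels = c("preemptive", "<1yr", "1-3yr", ">3yr"),
                  prob = norm_rows(rbind(
                    c(0.050, 0.159, 0.054, 0.737),
                    c(0.168, 0.310, 0.119, 0.404),
                    c(0.098, 0.247, 0.101, 0.555),
                    c(0.105, 0.334, 0.116, 0.445),
                    c(0.103, 0.286, 0.104, 0.507),
                    c(0.054, 0.246, 0.075, 0.625)))),
    variable_spec("esrd_cause", "categorical",
                  levels = c("diabetes", "hypertension", "glomerular", "pkd", "other"),
                  prob = norm_rows(rbind(
                    c(0.009, 0.664, 0.165, 0.083, 0.079),
                    c(0.029, 0.367, 0.229, 0.137, 0.238),
                    c(0.090, 0.171, 0.135, 0.039, 0.565),
                    c(0.239, 0.265, 0.227, 0.090, 0.179),
                    c(0.430, 0.237, 0.130, 0.079, 0.124),
                    c(0.972, 0.007, 0.008, 0.006, 0.007)))),
    variable_spec("diabetes", "binary",
                  prob = c(0.167, 0.147, 0.325, 0.302, 0.530, 1.0)),
    variable_spec("pra", "continuous",
                  mean = c(3, 0.5, 48, 0.5, 8, 0.5),
                  sd   = c(10, 3, 35, 3, 15, 3)),
    variable_spec("serum_albumin", "continuous",
                  mean = c(4.0, 4.0, 3.8, 4.0, 3.9, 3.9),
                  sd   = c(0.5, 0.5, 0.6, 0.5, 0.5, 0.6)),
    variable_spec("functional_status", "ordinal",
                  levels = c("10-30", "40-70", "80-100"),
                  prob = norm_rows(rbind(
                    c(0.002, 0.433, 0.565),
                    c(0.003, 0.332, 0.665),
                    c(0.001, 0.401, 0.598),
                    c(0.006, 0.302, 0.692),
                    c(0.003, 0.401, 0.596),
                    c(0.004, 0.485, 0.511)))),
    variable_spec("working_income", "binary",
                  prob = c(0.209, 0.200, 0.199, 0.298, 0.180, 0.127)),
    variable_spec("public_insurance", "binary",
                  prob = c(0.845, 0.783, 0.832, 0.693, 0.809, 0.844)),
    variable_spec("donor_age", "continuous",
                  mean = c(58.1, 62.6, 58.4, 0.7, 61.1, 60.7),
                  sd   = c(6.6, 6.3, 8.4, 3.1, 6.9, 6.7)),
    variable_spec("donor_race", "categorical",
                  levels = c("White", "Black", "Hispanic", "Other"),
                  prob = norm_rows(rbind(
                    c(0.305, 0.525, 0.105, 0.065),
                    c(0.689, 0.172, 0.093, 0.046),
                    c(0.443, 0.389, 0.098, 0.070),
                    c(0.310, 0.570, 0.096, 0.024),
                    c(0.633, 0.193, 0.129, 0.045),
                    c(0.496, 0.322, 0.123, 0.059)))),
    variable_spec("donor_hypertension", "binary",
                  prob = c(0.823, 0.772, 0.804, 0.018, 0.783, 0.793)),
    variable_spec("ecd_donor", "binary",
                  prob = c(0.756, 0.914, 0.776, 0.0, 0.855, 0.858)),
    variable_spec("dual_kidney", "binary",
                  prob = c(0.047, 0.089, 0.028, 0.836, 0.072, 0.062)),
    variable_spec("hla_mismatch", "ordinal",
                  levels = as.character(0:6),
                  prob = norm_rows(rbind(
                    c(0.01, 0.02, 0.05, 0.12, 0.25, 0.35, 0.20),
                    c(0.01, 0.03, 0.07, 0.15, 0.32, 0.32, 0.10),
                    c(0.02, 0.05, 0.15, 0.30, 0.28, 0.15, 0.05),
                    c(0.01, 0.02, 0.05, 0.12, 0.25, 0.35, 0.20),
                    c(0.05, 0.15, 0.30, 0.30, 0.15, 0.04, 0.01),
                    c(0.01, 0.02, 0.05, 0.12, 0.25, 0.35, 0.20)))),
    variable_spec("cold_ischemia_time", "continuous",
                  mean = c(19.6, 20.5, 20.4, 21.7, 19.7, 20.4),
                  sd   = c(9.0, 9.1, 9.1, 8.7, 8.4, 9.0)),
    variable_spec("kdpi", "continuous",
                  mean = c(91, 91, 90, 89, 91, 91),
                  sd   = c(4, 4, 4, 4, 4, 4)),
    variable_spec("kidney_on_pump", "binary",
                  prob = c(0.590, 0.656, 0.577, 0.427, 0.583, 0.617)),
    variable_spec("multi_organ", "binary",
                  prob = rep(0.01, 6)),
    variable_spec("transplant_year", "ordinal",
                  levels = as.character(2010:2019),
                  prob = matrix(rep(0.1, 10), nrow = 1))
  )
}

# dominant-level helper: dominant category gets `p`, the rest share 1 - p
dominant <- function(levels, idx, p = 0.9) {
  out <- matrix((1 - p) / (length(levels) - 1), nrow = length(idx), ncol = length(levels))
  for (i in seq_along(idx)) out[i, idx[i]] <- p
  out
}

# benchmark signatures: each phenotype near-deterministic on its marker set,
# contrasts balanced so no cluster pair is near-identical and none dominates
separated_registry_specs <- function() {
  race4 <- c("White", "Black", "Hispanic", "Other")
  list(
    variable_spec("recipient_age", "continuous",
                  mean = c(57, 68, 57, 52, 63, 63),
                  sd   = c(3, 3, 3, 3, 3, 3)),
    variable_spec("recipient_male", "binary",
                  prob = c(0.611, 0.642, 0.625, 0.508, 0.559, 0.695)),
    variable_spec("recipient_race", "categorical", levels = race4,
                  prob = dominant(race4, c(2, 1, 1, 4, 1, 3))),
    variable_spec("bmi", "continuous",
                  mean = c(28.6, 27.3, 27.4, 24.8, 28.7, 29.6),
                  sd   = rep(2, 6)),
    variable_spec("retransplant", "binary",
                  prob = c(0.02, 0.02, 0.97, 0.02, 0.02, 0.02)),
    variable_spec("dialysis_duration", "ordinal",
                  levels = c("preemptive", "<1yr", "1-3yr", ">3yr"),
                  prob = rbind(
                    c(0.02, 0.04, 0.04, 0.90),
                    c(0.50, 0.45, 0.04, 0.01),
                    c(0.02, 0.04, 0.04, 0.90),
                    c(0.04, 0.90, 0.04, 0.02),
                    c(0.02, 0.04, 0.90, 0.04),
                    c(0.02, 0.04, 0.04, 0.90))),
    variable_spec("esrd_cause", "categorical",
                  levels = c("diabetes", "hypertension", "glomerular", "pkd", "other"),
                  prob = dominant(1:5, c(2, 3, 5, 4, 1, 1))),
    variable_spec("diabetes", "binary",
                  prob = c(0.05, 0.05, 0.05, 0.05, 0.95, 1.0)),
    variable_spec("pra", "continuous",
                  mean = c(3, 1, 48, 1, 5, 1),
                  sd   = c(6, 6, 6, 6, 6, 6)),
    variable_spec("serum_albumin", "continuous",
                  mean = c(4.0, 4.0, 3.6, 4.0, 3.9, 3.9),
                  sd   = rep(0.15, 6)),
    variable_spec("functional_status", "ordinal",
                  levels = c("10-30", "40-70", "80-100"),
                  prob = rbind(
                    c(0.05, 0.90, 0.05),
                    c(0.02, 0.08, 0.90),
                    c(0.05, 0.90, 0.05),
                    c(0.02, 0.08, 0.90),
                    c(0.02, 0.08, 0.90),
                    c(0.05, 0.90, 0.05))),
    variable_spec("working_income", "binary",
                  prob = c(0.05, 0.05, 0.05, 0.30, 0.05, 0.05)),
    variable_spec("public_insurance", "binary",
                  prob = c(0.95, 0.80, 0.95, 0.70, 0.95, 0.95)),
    variable_spec("donor_age", "continuous",
                  mean = c(58, 63, 58, 0.7, 61, 61),
                  sd   = c(3, 3, 3, 0.5, 3, 3)),
    variable_spec("donor_race", "categorical", levels = race4,
                  prob = dominant(race4, c(2, 1, 2, 2, 1, 1))),
    variable_spec("donor_hypertension", "binary",
                  prob = c(0.90, 0.90, 0.90, 0.60, 0.90, 0.90)),
    variable_spec("ecd_donor", "binary",
                  prob = c(0.90, 0.90, 0.90, 0.02, 0.90, 0.90)),
    variable_spec("dual_kidney", "binary",
                  prob = c(0.03, 0.03, 0.03, 0.90, 0.03, 0.03)),
    variable_spec("hla_mismatch", "ordinal",
                  levels = as.character(0:6),
                  prob = rbind(
                    c(0.01, 0.01, 0.01, 0.02, 0.05, 0.45, 0.45),
                    c(0.01, 0.01, 0.02, 0.05, 0.45, 0.45, 0.01),
                    c(0.01, 0.02, 0.05, 0.45, 0.42, 0.04, 0.01),
                    c(0.01, 0.01, 0.01, 0.02, 0.05, 0.45, 0.45),
                    c(0.30, 0.40, 0.25, 0.03, 0.01, 0.005, 0.005),
                    c(0.01, 0.01, 0.01, 0.02, 0.05, 0.45, 0.45))),
    variable_spec("cold_ischemia_time", "continuous",
                  mean = c(19.6, 20.5, 20.4, 21.7, 19.7, 20.4),
                  sd   = rep(4, 6)),
    variable_spec("kdpi", "continuous",
                  mean = c(91, 91, 90, 89, 91, 91),
                  sd   = rep(4, 6)),
    variable_spec("kidney_on_pump", "binary",
                  prob = c(0.90, 0.90, 0.05, 0.05, 0.05, 0.90)),
    variable_spec("multi_organ", "binary",
                  prob = rep(0.01, 6)),
    variable_spec("transplant_year", "ordinal",
                  levels = as.character(2010:2019),
                  prob = matrix(rep(0.1, 10), nrow = 1))
  )
}

#' Default cluster weights (published cluster sizes of the 8935-patient cohort)
#' @return Length-6 probability vector.
#' @export
default_cluster_weights <- function() {
  sizes <- c(1984, 2135, 357, 335, 1069, 3055)
  sizes / sum(sizes)
}

#' Default per-cluster outcome parameters
#'
#' Exponential hazards for death and death-censored graft failure solved from
#' the published 5-year cluster survival percentages (`lambda = -log(S5)/5`);
#' event probabilities for primary non-function, delayed graft function and
#' 1-year acute rejection taken from the published cluster incidences.
#'
#' @return Named list of per-cluster parameter vectors.
#' @export
default_outcome_specs <- function() {
  s5_death <- c(0.792, 0.686, 0.621, 0.905, 0.689, 0.670)
  s5_dcgf  <- c(0.731, 0.843, 0.701, 0.818, 0.805, 0.762)
  list(
    death_rate = -log(s5_death) / 5,
    graft_failure_rate = -log(s5_dcgf) / 5,
    pnf_prob = c(0.018, 0.012, 0.014, 0.012, 0.007, 0.010),
    dgf_prob = c(0.383, 0.251, 0.417, 0.302, 0.318, 0.408),
    rejection_prob = c(0.079, 0.063, 0.106, 0.024, 0.065, 0.066)
  )
}

#' Default UNOS-region mix per cluster
#'
#' Mild cluster-specific tilts over the 11 allocation regions so the
#' region-by-cluster tabulation is exercised; not calibrated to any registry.
#'
#' @return 6 x 11 matrix with rows summing to 1.
#' @export
default_region_probs <- function() {
  base <- c(4, 6, 9, 10, 14, 5, 9, 7, 10, 11, 15) / 100
  tilt <- rbind(
    c(0, 0, 0, 0, 0, -2, 0, 0, 0, 0, 4),   # cluster 1 concentrated in region 11
    c(4, 0, 0, -2, 0, 0, 0, 0, 0, 0, 0),   # cluster 2 in region 1
    c(0, 0, -2, 0, 0, 0, 0, 4, 0, 0, 0),   # cluster 3 in region 8
    c(-2, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0),   # cluster 4 in region 5
    c(0, 0, -2, 0, 0, 4, 0, 0, 0, 0, 0),   # cluster 5 in region 6
    c(0, 0, 0, 0, 4, 0, 0, -2, 0, 0, 0)    # cluster 6 in region 5
  ) / 100
  p <- sweep(tilt, 2, base, "+")
  dimnames(p) <- list(paste0("cluster", 1:6), paste0("region", 1:11))
  norm_rows(pmax(p, 0.005))
}

cluster_param <- function(x, k) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) {
    if (nrow(x) == 1) x <- x[rep(1, k), , drop = FALSE]
    if (nrow(x) != k) stop("per-cluster parameter matrix has wrong row count", call. = FALSE)
    return(x)
  }
  if (length(x) == 1) x <- rep(x, k)
  if (length(x) != k) stop("per-cluster parameter has wrong length", call. = FALSE)
  x
}

#' Generate a synthetic registry cohort with planted clusters
#'
#' Draws each subject's cluster from `cluster_weights`, then each variable
#' from that cluster's parameters (normal for continuous, categorical draws
#' otherwise); assigns a UNOS region and simulates post-transplant outcomes.
#' The returned table is complete — use [inject_missingness()] to mask cells.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_cohort`: list with `cohort`
#'   (a [cohort_table()]), `true_labels`, `outcomes` (data.frame), `region`
#'   (integer 1-11 per subject), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$n_clusters_true
  n <- config$n_subjects
  seeds <- derive_seeds(config$seed, 3)

  set.seed(seeds[1])
  z <- sample.int(k, n, replace = TRUE, prob = config$cluster_weights)
  if (n >= 10 * k && length(unique(z)) < k) {
    # guarantee non-empty clusters at reasonable sizes
    missing_cl <- setdiff(seq_len(k), unique(z))
    z[sample.int(n, length(missing_cl))] <- missing_cl
  }

  data <- list()
  for (vs in config$variable_specs) {
    if (vs$kind == "continuous") {
      mu <- cluster_param(vs$mean, k)
      sg <- cluster_param(vs$sd, k)
      data[[vs$name]] <- stats::rnorm(n, mean = mu[z], sd = sg[z])
    } else {
      pr <- cluster_param(vs$prob, k)
      if (is.null(pr)) stop("variable '", vs$name, "' lacks level probabilities", call. = FALSE)
      col <- character(n)
      for (c_idx in seq_len(k)) {
        idx <- which(z == c_idx)
        if (length(idx)) {
          col[idx] <- sample(vs$levels, length(idx), replace = TRUE, prob = pr[c_idx, ])
        }
      }
      data[[vs$name]] <- col
    }
  }
  schema <- schema_from_specs(config$variable_specs)
  cohort <- cohort_table(as.data.frame(data, stringsAsFactors = FALSE), schema,
                         admin_vars = config$admin_vars)

  set.seed(seeds[2])
  region <- integer(n)
  for (c_idx in seq_len(k)) {
    idx <- which(z == c_idx)
    if (length(idx)) {
      region[idx] <- sample.int(11, length(idx), replace = TRUE,
                                prob = config$region_probs[c_idx, ])
    }
  }

  outcomes <- generate_outcomes(z, config$outcome_specs, config$admin_censor_time,
                                seed = seeds[3])

  structure(
    list(cohort = cohort, true_labels = z, outcomes = outcomes,
         region = region, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", length(x$true_labels),
      "| planted clusters:", x$config$n_clusters_true, "\n")
  print(table(cluster = x$true_labels))
  invisible(x)
}

#' Mask cohort cells completely at random
#'
#' Each eligible cell (every schema column except `admin_vars`; outcome and
#' ID columns never enter the cohort table) is masked independently with
#' probability `rate`. The mask is recorded in `missing_mask`.
#'
#' @param cohort A [cohort_table()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `cohort_table` with NAs where masked.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(cohort)
  set.seed(seed)
  eligible <- setdiff(names(cohort$data), cohort$admin_vars)
  n <- nrow(cohort$data)
  for (v in eligible) {
    hit <- stats::runif(n) < rate
    cohort$data[[v]][hit] <- NA
    cohort$missing_mask[hit, v] <- TRUE
  }
  cohort
}

#' Simulate per-cluster post-transplant outcomes
#'
#' Latent event times for death and graft failure are exponential with the
#' cluster's rates; the three time-to-event outcome columns are derived
#' consistently from the two clocks: patient death is administratively
#' censored at `admin_censor_time`; death-censored graft failure treats an
#' earlier death as censoring at the death time; all-cause graft failure is
#' the first of the two events. Binary outcomes (primary non-function,
#' delayed graft function, 1-year acute rejection) are Bernoulli with the
#' cluster's probability.
#'
#' @param labels Integer cluster index per subject.
#' @param outcome_specs Named list as in [default_outcome_specs()].
#' @param admin_censor_time Censoring horizon (years, > 0).
#' @param seed Integer seed.
#' @return Data.frame with columns `death_time`, `death_event`,
#'   `dc_graft_time`, `dc_graft_event`, `graft_time`, `graft_event`,
#'   `primary_non_function`, `delayed_graft_function`, `rejection_1yr`.
#' @export
generate_outcomes <- function(labels, outcome_specs = default_outcome_specs(),
                              admin_censor_time = 10, seed = 1L) {
  k <- max(labels)
  validate_outcome_specs(outcome_specs, k)
  stopifnot(admin_censor_time > 0)
  n <- length(labels)
  gp <- function(f) cluster_param(outcome_specs[[f]], k)[labels]

  set.seed(seed)
  t_death <- stats::rexp(n, rate = gp("death_rate"))
  t_graft <- stats::rexp(n, rate = gp("graft_failure_rate"))
  cens <- admin_censor_time

  death_event <- as.integer(t_death <= cens)
  death_time <- pmin(t_death, cens)

  # death-censored graft failure: death with functioning graft censors
  dc_limit <- pmin(t_death, cens)
  dc_graft_event <- as.integer(t_graft <= dc_limit)
  dc_graft_time <- pmin(t_graft, dc_limit)

  # all-cause graft failure: first of graft failure or death
  t_all <- pmin(t_graft, t_death)
  graft_event <- as.integer(t_all <= cens)
  graft_time <- pmin(t_all, cens)

  data.frame(
    death_time = death_time, death_event = death_event,
    dc_graft_time = dc_graft_time, dc_graft_event = dc_graft_event,
    graft_time = graft_time, graft_event = graft_event,
    primary_non_function = as.integer(stats::runif(n) < gp("pnf_prob")),
    delayed_graft_function = as.integer(stats::runif(n) < gp("dgf_prob")),
    rejection_1yr = as.integer(stats::runif(n) < gp("rejection_prob"))
  )
}

#' Read a simulation configuration from YAML
#'
#' Recognized top-level fields mirror [simulation_config()] arguments;
#' `variable_specs` entries are lists with `name`, `kind` and the relevant
#' parameter fields (`mean`/`sd` or `levels`/`prob`, probabilities as a list
#' of per-cluster rows). Omitted fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- if (!is.null(y$variable_specs)) {
    lapply(y$variable_specs, function(e) {
      prob <- e$prob
      if (is.list(prob)) prob <- do.call(rbind, lapply(prob, unlist))
      variable_spec(e$name, e$kind, levels = unlist(e$levels),
                    mean = unlist(e$mean), sd = unlist(e$sd), prob = prob)
    })
  } else default_registry_specs()
  os <- y$outcome_specs
  outcome_specs <- if (is.null(os)) default_outcome_specs() else lapply(os, unlist)
  simulation_config(
    n_subjects = y$n_subjects %||% 600,
    n_clusters_true = y$n_clusters_true %||% 6,
    cluster_weights = unlist(y$cluster_weights),
    variable_specs = specs,
    missing_rate = y$missing_rate %||% 0.05,
    outcome_specs = outcome_specs,
    admin_censor_time = y$admin_censor_time %||% 10,
    seed = y$seed %||% 1L
  )
}
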