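#' Characterization settings
#'
#' @param smd_cutoff Absolute standardized-mean-difference threshold above
#'   which a variable is flagged as a key cluster feature (default 0.3).
#' @param comparison `"cluster_vs_overall"` (cluster against the whole
#'   cohort, cluster members included in the reference — the default) or
#'   `"cluster_vs_rest"` (cluster against all other subjects; SMDs are not
#'   attenuated by overlap).
#' @return An object of class `characterization_config`.
#' @export
characterization_config <- function(smd_cutoff = 0.3,
                                    comparison = c("cluster_vs_overall", "cluster_vs_rest")) {
  if (smd_cutoff <= 0) stop("smd_cutoff must be > 0", call. = FALSE)
  structure(list(smd_cutoff = smd_cutoff, comparison = match.arg(comparison)),
            class = "characterization_config")
}

#' Standardized mean difference of a continuous summary
#'
#' `(mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)` — the two-group
#' quadratic-mean pooling standard in cohort balance tables. When the pooled
#' SD is zero the difference is 0 for equal means and `NA` (undefined;
#' excluded from key features) otherwise.
#'
#' @param mean_a,sd_a Group-A mean and standard deviation (`sd_a >= 0`).
#' @param mean_b,sd_b Group-B mean and standard deviation.
#' @return Signed dimensionless SMD.
#' @export
smd_continuous <- function(mean_a, sd_a, mean_b, sd_b) {
  stopifnot(sd_a >= 0, sd_b >= 0)
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (pooled == 0) return(if (mean_a == mean_b) 0 else NA_real_)
  (mean_a - mean_b) / pooled
}

#' Standardized mean difference of a proportion
#'
#' `(p_a - p_b) / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2)`; categorical variables
#' enter as one indicator per level. A zero denominator (both proportions 0
#' or both 1) yields 0 when `p_a == p_b` and `NA` (undefined) otherwise.
#'
#' @param p_a,p_b Proportions in `[0, 1]`.
#' @return Signed dimensionless SMD.
#' @export
smd_proportion <- function(p_a, p_b) {
  stopifnot(p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  denom <- sqrt((p_a * (1 - p_a) + p_b * (1 - p_b)) / 2)
  if (denom == 0) return(if (p_a == p_b) 0 else NA_real_)
  (p_a - p_b) / denom
}

fmt_mean_sd <- function(x) paste0(round_half_up(mean(x), 1), " ± ", round_half_up(stats::sd(x), 1))
fmt_count_pct <- function(k, n) paste0(k, " (", round_half_up(100 * k / n, 1), ")")

#' Standardized-mean-difference profile of each cluster
#'
#' Describes every cluster against the reference group (the overall cohort by
#' default): continuous variables via [smd_continuous()] on the group means
#' and SDs, binary variables via [smd_proportion()] on the positive-level
#' proportion, categorical and ordinal variables via one indicator SMD per
#' level. Entries are sorted by `|smd|` descending (undefined SMDs last) and
#' those with `|smd| > smd_cutoff` are flagged as key features.
#'
#' @param cohort A complete [cohort_table()].
#' @param assignment A `cluster_assignment` (or bare integer label vector)
#'   covering all subjects.
#' @param config A [characterization_config()].
#' @param vars Variables to profile; default all non-admin schema columns.
#' @return Object of class `smd_profiles`: per-cluster list with
#'   `cluster_id`, `n`, `table` (data.frame: `variable`, `level`,
#'   `cluster_summary`, `overall_summary`, `smd`, `key_feature`), and
#'   `key_features` (the flagged subset).
#' @export
smd_profile <- function(cohort, assignment, config = characterization_config(),
                        vars = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else as.integer(assignment)
  if (length(labels) != nrow(cohort$data)) {
    stop("assignment must cover all subjects", call. = FALSE)
  }
  if (anyNA(cohort$data)) stop("cohort has missing cells; impute first", call. = FALSE)
  if (is.null(vars)) vars <- setdiff(names(cohort$data), cohort$admin_vars)
  ks <- sort(unique(labels))
  if (any(tabulate(labels) == 0)) stop("empty cluster in assignment", call. = FALSE)

  profiles <- lapply(ks, function(c_idx) {
    in_c <- labels == c_idx
    ref <- if (config$comparison == "cluster_vs_overall") rep(TRUE, length(labels)) else !in_c
    rows <- list()
    for (v in vars) {
      kind <- cohort$schema[[v]]$kind
      x <- cohort$data[[v]]
      if (kind == "continuous") {
        a <- x[in_c]; b <- x[ref]
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = NA_character_,
          cluster_summary = fmt_mean_sd(a), overall_summary = fmt_mean_sd(b),
          smd = smd_continuous(mean(a), stats::sd(a), mean(b), stats::sd(b)),
          stringsAsFactors = FALSE)
      } else {
        lvls <- if (kind == "binary") levels(x)[2] else levels(x)
        for (lv in lvls) {
          pa <- mean(x[in_c] == lv); pb <- mean(x[ref] == lv)
          rows[[length(rows) + 1]] <- data.frame(
            variable = v, level = lv,
            cluster_summary = fmt_count_pct(sum(x[in_c] == lv), sum(in_c)),
            overall_summary = fmt_count_pct(sum(x[ref] == lv), sum(ref)),
            smd = smd_proportion(pa, pb),
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    tab$key_feature <- !is.na(tab$smd) & abs(tab$smd) > config$smd_cutoff
    tab <- tab[order(-abs(tab$smd), na.last = TRUE), ]
    rownames(tab) <- NULL
    list(cluster_id = c_idx, n = sum(in_c), table = tab,
         key_features = tab[tab$key_feature, ])
  })
  names(profiles) <- paste0("cluster", ks)
  structure(profiles, class = "smd_profiles", cutoff = config$smd_cutoff)
}

#' @export
print.smd_profiles <- function(x, ...) {
  cat("<smd_profiles> cutoff |SMD| >", attr(x, "cutoff"), "\n")
  for (p in x) {
    kf <- p$key_features
    lab <- ifelse(is.na(kf$level), kf$variable, paste0(kf$variable, "=", kf$level))
    cat("  cluster ", p$cluster_id, " (n=", p$n, "): ",
        if (nrow(kf)) paste0(lab, " (", round(kf$smd, 2), ")", collapse = ", ")
        else "no key features", "\n", sep = "")
  }
  invisible(x)
}

#' Cluster mix by UNOS region
#'
#' For each allocation region, the fraction of its recipients assigned to
#' each cluster (rows sum to 1) together with the per-region transplant
#' count.
#'
#' @param assignment A `cluster_assignment` or integer label vector.
#' @param region_labels One region label per subject; numeric labels must be
#'   integers 1..11 (the UNOS regions), otherwise factor/character levels are
#'   used as given.
#' @return Data.frame: `region`, `n_transplants`, then one proportion column
#'   per cluster.
#' @export
region_proportions <- function(assignment, region_labels) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else as.integer(assignment)
  if (length(labels) != length(region_labels)) {
    stop("one region label per subject required", call. = FALSE)
  }
  if (is.numeric(region_labels)) {
    if (any(!(region_labels %in% 1:11))) {
      stop("unknown region label: ",
           paste(unique(setdiff(region_labels, 1:11)), collapse = ", "), call. = FALSE)
    }
    region_labels <- factor(region_labels, levels = sort(unique(region_labels)))
  } else {
    region_labels <- factor(as.character(region_labels))
  }
  tab <- table(region = region_labels, cluster = labels)
  props <- sweep(tab, 1, rowSums(tab), "/")
  out <- data.frame(region = rownames(tab),
                    n_transplants = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (cl in colnames(props)) out[[paste0("cluster", cl)]] <- as.numeric(props[, cl])
  out
}

#' Write per-cluster SMD tables and the region-by-cluster proportions
#'
#' @param profiles An [smd_profile()] result.
#' @param dir Output directory.
#' @param regions Optional [region_proportions()] result.
#' @return `dir`, invisibly.
#' @export
write_characterization <- function(profiles, dir, regions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in profiles) {
    utils::write.csv(p$table,
                     file.path(dir, paste0("smd_cluster", p$cluster_id, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(regions)) {
    utils::write.csv(regions, file.path(dir, "region_proportions.csv"), row.names = FALSE)
  }
  invisible(dir)
}
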