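#' Consensus clustering configuration
#'
#' Settings for subsampling-based consensus clustering: the candidate-k grid
#' (default 2..10), 100 resampling iterations at an 80% subsampling fraction,
#' the ambiguity band used for the PAC statistic, the base clusterer applied
#' to each subsample, and the master seed.
#'
#' @param k_min,k_max Candidate cluster-number grid (default 2..10).
#' @param n_iterations Number of subsampling iterations (default 100).
#' @param subsample_fraction Fraction of subjects drawn without replacement
#'   each iteration, in `(0, 1]` (default 0.8).
#' @param pac_lower,pac_upper Consensus-value band defining an "ambiguously
#'   clustered" pair (defaults 0.1 and 0.9).
#' @param base_clusterer `"pam"` (partitioning around medoids on the
#'   dissimilarity; default) or `"hierarchical_average"` (average-linkage tree
#'   cut at k).
#' @param seed Master seed; per-iteration subsample seeds are derived from it
#'   by a fixed counter scheme.
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(k_min = 2, k_max = 10, n_iterations = 100,
                             subsample_fraction = 0.8,
                             pac_lower = 0.1, pac_upper = 0.9,
                             base_clusterer = c("pam", "hierarchical_average"),
                             seed = 1L) {
  base_clusterer <- match.arg(base_clusterer)
  if (!(2 <= k_min && k_min <= k_max)) stop("need 2 <= k_min <= k_max", call. = FALSE)
  if (!(subsample_fraction > 0 && subsample_fraction <= 1)) {
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!(0 <= pac_lower && pac_lower < pac_upper && pac_upper <= 1)) {
    stop("need 0 <= pac_lower < pac_upper <= 1", call. = FALSE)
  }
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_iterations = as.integer(n_iterations),
                 subsample_fraction = subsample_fraction,
                 pac_lower = pac_lower, pac_upper = pac_upper,
                 base_clusterer = base_clusterer, seed = as.integer(seed)),
            class = "consensus_config")
}

dist_values <- function(distance) {
  if (inherits(distance, "distance_matrix")) distance$values
  else as.matrix(distance)
}

#' Cluster a dissimilarity matrix once
#'
#' The inner clusterer applied to each subsample: partitioning around medoids
#' (deterministic build + swap on the dissimilarity) or average-linkage
#' hierarchical clustering cut at `k`. Returns integer labels 1..k with every
#' cluster non-empty.
#'
#' @param sub_distance A `distance_matrix`, dissimilarity matrix, or `dist`.
#' @param k Number of clusters (`k <= n`).
#' @param method `"pam"` or `"hierarchical_average"`.
#' @param seed Unused by the deterministic methods; kept so alternative
#'   stochastic clusterers honor the same contract.
#' @return Integer vector of cluster labels.
#' @export
base_cluster <- function(sub_distance, k, method = c("pam", "hierarchical_average"),
                         seed = NULL) {
  method <- match.arg(method)
  d <- dist_values(sub_distance)
  n <- nrow(d)
  if (k > n) stop("k (", k, ") exceeds number of subjects (", n, ")", call. = FALSE)
  if (k == n) return(seq_len(n))
  if (method == "pam") {
    as.integer(cluster::pam(stats::as.dist(d), k, diss = TRUE,
                            cluster.only = TRUE))
  } else {
    as.integer(stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k))
  }
}

# final assignment convention: average linkage on (1 - consensus), cut at k,
# clusters renumbered by descending size (ties broken by first appearance)
consensus_assignment <- function(M, k) {
  tree <- stats::hclust(stats::as.dist(1 - M), method = "average")
  raw <- stats::cutree(tree, k)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- relabel[raw]
  structure(list(labels = labels, k = k,
                 sizes = as.integer(table(factor(labels, levels = seq_len(k))))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k =", x$k, "| sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Run subsampling-based consensus clustering over a k grid
#'
#' For each of `n_iterations` iterations, `floor(subsample_fraction * n)`
#' subjects are drawn without replacement and the induced sub-dissimilarity
#' is clustered at every k in the grid. The consensus value of a subject pair
#' at a given k is its co-clustering count divided by its co-sampling count
#' (0 for pairs never co-sampled, which are counted and reported). The final
#' assignment at each k is obtained by average-linkage hierarchical
#' clustering of `1 - consensus` cut at k, relabeled by descending cluster
#' size. Deterministic given the config seed.
#'
#' @param distance A `distance_matrix` (see [gower_distance()]).
#' @param config A [consensus_config()].
#' @return An object of class `consensus_run`: per-k list with elements
#'   `matrix` (class `consensus_matrix`: `values`, `cosample_counts`, `k`)
#'   and `assignment` (class `cluster_assignment`), plus the `config`.
#' @export
run_consensus <- function(distance, config = consensus_config()) {
  stopifnot(inherits(config, "consensus_config"))
  d <- dist_values(distance)
  n <- nrow(d)
  if (n < config$k_max + 1) stop("need n >= k_max + 1 subjects", call. = FALSE)
  m <- floor(config$subsample_fraction * n)
  if (m < config$k_max) stop("subsample size ", m, " smaller than k_max ", config$k_max, call. = FALSE)

  ks <- config$k_min:config$k_max
  iter_seeds <- derive_seeds(config$seed, config$n_iterations)
  cosample <- matrix(0L, n, n)
  cocluster <- lapply(ks, function(k) matrix(0L, n, n))
  names(cocluster) <- as.character(ks)

  for (i in seq_len(config$n_iterations)) {
    set.seed(iter_seeds[i])
    idx <- sample.int(n, m)
    cosample[idx, idx] <- cosample[idx, idx] + 1L
    sub <- d[idx, idx]
    if (config$base_clusterer == "hierarchical_average") {
      tree <- stats::hclust(stats::as.dist(sub), method = "average")
      cuts <- stats::cutree(tree, ks)
      for (j in seq_along(ks)) {
        labs <- cuts[, j]
        conn <- outer(labs, labs, "==")
        cocluster[[j]][idx, idx] <- cocluster[[j]][idx, idx] + conn
      }
    } else {
      subd <- stats::as.dist(sub)
      for (j in seq_along(ks)) {
        labs <- if (ks[j] == m) seq_len(m) else {
          as.integer(cluster::pam(subd, ks[j], diss = TRUE,
                                  cluster.only = TRUE))
        }
        conn <- outer(labs, labs, "==")
        cocluster[[j]][idx, idx] <- cocluster[[j]][idx, idx] + conn
      }
    }
  }

  never <- sum(cosample[upper.tri(cosample)] == 0)
  if (never > 0) {
    message(never, " subject pair(s) never co-sampled; their consensus is defined 0")
  }

  runs <- lapply(seq_along(ks), function(j) {
    M <- matrix(0, n, n)
    pos <- cosample > 0
    M[pos] <- cocluster[[j]][pos] / cosample[pos]
    M <- (M + t(M)) / 2
    diag(M) <- 1
    dimnames(M) <- dimnames(d)
    cm <- structure(list(values = M, cosample_counts = cosample, k = ks[j]),
                    class = "consensus_matrix")
    list(matrix = cm, assignment = consensus_assignment(M, ks[j]))
  })
  names(runs) <- as.character(ks)
  structure(list(runs = runs, config = config,
                 subject_id = rownames(d) %||% as.character(seq_len(n))),
            class = "consensus_run")
}

#' @export
print.consensus_run <- function(x, ...) {
  cat("<consensus_run> k grid:", names(x$runs)[1], "..", utils::tail(names(x$runs), 1),
      "|", x$config$n_iterations, "iterations at",
      100 * x$config$subsample_fraction, "% subsampling\n")
  invisible(x)
}

#' Stability diagnostics over the k grid
#'
#' From each stored consensus matrix: the empirical CDF of off-diagonal
#' consensus values on a fixed 101-point grid over `[0, 1]`; the trapezoid
#' area under that CDF and its relative change versus k-1 (at `k_min` the
#' area itself); the proportion of ambiguously clustered pairs
#' (`pac_lower < value < pac_upper`, strict); and per-cluster within-cluster
#' consensus scores (mean consensus over subject pairs inside the cluster;
#' a singleton cluster scores 1 by convention, reported via `message()`)
#' with their unweighted mean.
#'
#' @param run A [run_consensus()] result (or a bare per-k list of
#'   `consensus_matrix` objects, from which assignments are recomputed).
#' @param config A [consensus_config()] (defaults to the run's own).
#' @return Object of class `k_diagnostics`: `summary` data.frame
#'   (`k`, `pac`, `cdf_area`, `delta_area`, `mean_cluster_consensus`),
#'   `cluster_consensus` (per-k vector of per-cluster scores), and `cdf`
#'   (per-k data.frame `grid`, `cdf`).
#' @export
compute_diagnostics <- function(run, config = NULL) {
  if (inherits(run, "consensus_run")) {
    config <- config %||% run$config
    runs <- run$runs
  } else {
    if (is.null(config)) stop("config required when passing bare consensus matrices", call. = FALSE)
    runs <- lapply(run, function(cm) {
      list(matrix = cm, assignment = consensus_assignment(cm$values, cm$k))
    })
    names(runs) <- vapply(run, function(cm) as.character(cm$k), "")
  }
  ks <- as.integer(names(runs))
  if (any(diff(ks) != 1)) stop("k grid must be contiguous", call. = FALSE)

  grid <- seq(0, 1, length.out = 101)
  cdf_list <- list()
  cc_list <- list()
  pac <- area <- mean_cc <- numeric(length(ks))

  for (j in seq_along(ks)) {
    M <- runs[[j]]$matrix$values
    v <- M[upper.tri(M)]
    cdf <- vapply(grid, function(g) mean(v <= g), 0)
    cdf_list[[j]] <- data.frame(k = ks[j], grid = grid, cdf = cdf)
    area[j] <- sum(diff(grid) * (cdf[-1] + cdf[-length(cdf)]) / 2)
    pac[j] <- mean(v > config$pac_lower & v < config$pac_upper)

    labs <- runs[[j]]$assignment$labels
    scores <- vapply(seq_len(ks[j]), function(c_idx) {
      members <- which(labs == c_idx)
      if (length(members) < 2) {
        message("cluster ", c_idx, " at k=", ks[j], " is a singleton; consensus score 1 by convention")
        return(1)
      }
      sub <- M[members, members]
      mean(sub[upper.tri(sub)])
    }, 0)
    cc_list[[j]] <- scores
    mean_cc[j] <- mean(scores)
  }

  delta <- c(area[1], diff(area) / area[-length(area)])
  names(cc_list) <- names(cdf_list) <- as.character(ks)
  structure(
    list(summary = data.frame(k = ks, pac = pac, cdf_area = area,
                              delta_area = delta,
                              mean_cluster_consensus = mean_cc),
         cluster_consensus = cc_list,
         cdf = cdf_list),
    class = "k_diagnostics"
  )
}

#' @export
print.k_diagnostics <- function(x, ...) {
  cat("<k_diagnostics>\n")
  print(transform(x$summary,
                  pac = round(pac, 4), cdf_area = round(cdf_area, 4),
                  delta_area = round(delta_area, 4),
                  mean_cluster_consensus = round(mean_cluster_consensus, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Choose the number of clusters from stability diagnostics
#'
#' Rules: `"mean_consensus"` (default) — the k maximizing the mean
#' within-cluster consensus score; `"pac"` — the k minimizing PAC;
#' `"composite"` — the k minimizing the rank-sum of (low PAC, high mean
#' consensus, small delta-area gain), reported with the per-criterion table
#' so a reviewer can adjudicate the qualitative call. Ties go to the
#' smallest k.
#'
#' @param diag A [compute_diagnostics()] result.
#' @param rule One of `"mean_consensus"`, `"pac"`, `"composite"`.
#' @return The chosen k (integer), with the criterion table attached as
#'   attribute `"criteria"`.
#' @export
select_k <- function(diag, rule = c("mean_consensus", "pac", "composite")) {
  rule <- match.arg(rule)
  s <- diag$summary
  if (nrow(s) < 2) stop("diagnostics must cover at least 2 values of k", call. = FALSE)
  score <- switch(rule,
    mean_consensus = -s$mean_cluster_consensus,
    pac = s$pac,
    composite = rank(s$pac, ties.method = "average") +
      rank(-s$mean_cluster_consensus, ties.method = "average") +
      rank(s$delta_area, ties.method = "average")
  )
  best <- s$k[which.min(score)] # which.min takes the first (smallest k) on ties
  structure(as.integer(best), criteria = cbind(s, score = score))
}

#' Write consensus results as plot-ready CSV files
#'
#' Emits, under `dir`: `consensus_k<k>.csv` (dense consensus matrices),
#' `diagnostics.csv` (k-selection table with per-cluster consensus scores),
#' `cdf.csv` (long-format CDF curves), and `assignment_k<k>.csv`
#' (`subject_id`, `cluster`) for the chosen k.
#'
#' @param run A [run_consensus()] result.
#' @param diag A [compute_diagnostics()] result.
#' @param dir Output directory (created if needed).
#' @param chosen_k k whose assignment to write (default [select_k()] default
#'   rule).
#' @return `dir`, invisibly.
#' @export
write_consensus_results <- function(run, diag, dir, chosen_k = select_k(diag)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (entry in run$runs) {
    utils::write.csv(as.data.frame(entry$matrix$values),
                     file.path(dir, paste0("consensus_k", entry$matrix$k, ".csv")),
                     row.names = FALSE)
  }
  cc <- vapply(diag$cluster_consensus, function(v) {
    paste(round(v, 6), collapse = ";")
  }, "")
  utils::write.csv(cbind(diag$summary, cluster_consensus = cc),
                   file.path(dir, "diagnostics.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, diag$cdf), file.path(dir, "cdf.csv"),
                   row.names = FALSE)
  a <- run$runs[[as.character(chosen_k)]]$assignment
  utils::write.csv(data.frame(subject_id = run$subject_id, cluster = a$labels),
                   file.path(dir, paste0("assignment_k", chosen_k, ".csv")),
                   row.names = FALSE)
  invisible(dir)
}
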