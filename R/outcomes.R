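test_result <- function(statistic, df, p_value, test_name, note = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_name = test_name, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$test_name, ": statistic =", signif(x$statistic, 5),
      "df =", paste(x$df, collapse = ","),
      "p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] with the standard conventions: censored
#' subjects leave the risk set after their time, and a tie between an event
#' and a censoring at the same time counts the event first. Greenwood
#' standard errors are carried along.
#'
#' @param times Non-negative follow-up times (years).
#' @param events 0/1 event indicators (0 = censored).
#' @return Object of class `km_estimate`: `event_times` (distinct times with
#'   at least one event), `survival` (product-limit value just after each),
#'   `at_risk`, `n_events`, `greenwood_se`, `n`, `max_time` (largest observed
#'   time, events or censorings).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  stopifnot(all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  has_event <- fit$n.event > 0
  structure(
    list(event_times = fit$time[has_event],
         survival = fit$surv[has_event],
         at_risk = fit$n.risk[has_event],
         n_events = fit$n.event[has_event],
         greenwood_se = fit$std.err[has_event] * fit$surv[has_event],
         n = length(times),
         max_time = max(times)),
    class = "km_estimate"
  )
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("<km_estimate> n =", x$n, "|", sum(x$n_events), "events over",
      length(x$event_times), "distinct times\n")
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function value; beyond the last observed follow-up
#' time the last value is carried forward and flagged via the
#' `"extrapolated"` attribute.
#'
#' @param km A [km_estimate()].
#' @param t Non-negative times (years).
#' @return Survival probabilities, with logical attribute `"extrapolated"`.
#' @export
survival_at <- function(km, t) {
  stopifnot(all(t >= 0))
  s <- if (length(km$event_times) == 0) {
    rep(1, length(t))
  } else {
    # right-continuous: value after the last event time <= t
    idx <- findInterval(t, km$event_times)
    c(1, km$survival)[idx + 1]
  }
  structure(s, extrapolated = t > km$max_time)
}

#' G-group log-rank test
#'
#' Observed-minus-expected events per group accumulated across the pooled
#' event times with the hypergeometric variance; the statistic is referred
#' to a chi-squared distribution with G-1 degrees of freedom. Computed via
#' [survival::survdiff()]. When no group has any event the comparison is
#' undefined and `p = 1` is returned with a note.
#'
#' @param groups List of length >= 2; each element a list or data.frame with
#'   components `times` and `events`.
#' @return A `test_result`.
#' @export
logrank_test <- function(groups) {
  stopifnot(length(groups) >= 2)
  times <- unlist(lapply(groups, function(g) g$times))
  events <- unlist(lapply(groups, function(g) g$events))
  grp <- factor(rep(seq_along(groups), vapply(groups, function(g) length(g$times), 0L)))
  if (any(tabulate(grp) == 0)) stop("each group needs at least one subject", call. = FALSE)
  df <- length(groups) - 1
  if (sum(events) == 0) {
    return(test_result(NA_real_, df, 1, "log-rank", note = "no events in any group"))
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ grp)
  test_result(fit$chisq, df, stats::pchisq(fit$chisq, df, lower.tail = FALSE),
              "log-rank")
}

#' Pearson chi-squared test on a contingency table
#'
#' `sum((O - E)^2 / E)` with `(r-1)(c-1)` degrees of freedom, no continuity
#' correction, via [stats::chisq.test()].
#'
#' @param contingency r x c matrix of non-negative counts; every row and
#'   column margin must be positive.
#' @return A `test_result`.
#' @export
chi_squared_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(contingency < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value, "chi-squared")
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test: between-group mean square over
#' within-group mean square on (G-1, N-G) degrees of freedom, via
#' [stats::oneway.test()]. Degenerate inputs with zero within-group variance
#' give F = 0 (equal means) or an infinite-F flag (unequal means).
#'
#' @param groups List of >= 2 numeric vectors; total n must exceed the number
#'   of groups.
#' @return A `test_result`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 0L) >= 1))
  ns <- vapply(groups, length, 0L)
  if (sum(ns) <= length(groups)) stop("total n must exceed the number of groups", call. = FALSE)
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), ns))
  within_ss <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  means <- vapply(groups, mean, 0)
  df <- c(length(groups) - 1, sum(ns) - length(groups))
  if (within_ss == 0) {
    if (max(means) - min(means) == 0) {
      return(test_result(0, df, 1, "one-way ANOVA", note = "zero variance everywhere"))
    }
    return(test_result(Inf, df, 0, "one-way ANOVA",
                       note = "zero within-group variance with unequal means"))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  test_result(unname(fit$statistic), unname(fit$parameter), fit$p.value,
              "one-way ANOVA")
}

required_outcome_cols <- c(
  "death_time", "death_event", "dc_graft_time", "dc_graft_event",
  "graft_time", "graft_event",
  "primary_non_function", "delayed_graft_function", "rejection_1yr"
)

tte_outcomes <- c(death = "death", dc_graft = "dc_graft", graft = "graft")
binary_outcomes <- c("primary_non_function", "delayed_graft_function", "rejection_1yr")

#' Cluster-wise post-transplant outcome summary
#'
#' The registry-style outcome table: per cluster, counts and half-up
#' one-decimal percentages for the binary outcomes (primary non-function,
#' delayed graft function, 1-year acute rejection; 1-year rejection is
#' binary because the registry records occurrence, not date) and Kaplan-Meier
#' survival at the requested horizons for patient death, death-censored
#' graft failure and all-cause graft failure; chi-squared tests compare the
#' binary outcomes across clusters and log-rank tests the survival outcomes.
#' No multiplicity correction is applied to the headline p-values (a
#' Bonferroni column is reported alongside).
#'
#' @param outcomes Data.frame with the nine outcome columns produced by
#'   [generate_outcomes()] (or a registry extract in the same layout).
#' @param assignment A `cluster_assignment` or integer label vector covering
#'   all subjects.
#' @param horizons Survival horizons in years (default `c(1, 5)`).
#' @return Object of class `outcome_summary`: `binary` (data.frame
#'   `outcome`, `cluster`, `n`, `events`, `pct`), `survival` (data.frame
#'   `outcome`, `cluster`, `horizon`, `survival_pct`), `tests` (data.frame
#'   `outcome`, `test`, `statistic`, `df`, `p_value`, `p_bonferroni`), and
#'   `km` (per outcome, per cluster [km_estimate()]).
#' @export
outcome_summary <- function(outcomes, assignment, horizons = c(1, 5)) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else as.integer(assignment)
  stopifnot(length(labels) == nrow(outcomes))
  missing_cols <- setdiff(required_outcome_cols, names(outcomes))
  if (length(missing_cols)) {
    stop("missing outcome column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ks <- sort(unique(labels))

  binary <- do.call(rbind, lapply(binary_outcomes, function(oc) {
    do.call(rbind, lapply(ks, function(cl) {
      n <- sum(labels == cl)
      ev <- sum(outcomes[[oc]][labels == cl])
      data.frame(outcome = oc, cluster = cl, n = n, events = ev,
                 pct = pct(ev, n), stringsAsFactors = FALSE)
    }))
  }))

  km <- lapply(names(tte_outcomes), function(oc) {
    fits <- lapply(ks, function(cl) {
      km_estimate(outcomes[[paste0(oc, "_time")]][labels == cl],
                  outcomes[[paste0(oc, "_event")]][labels == cl])
    })
    names(fits) <- paste0("cluster", ks)
    fits
  })
  names(km) <- names(tte_outcomes)

  surv <- do.call(rbind, lapply(names(tte_outcomes), function(oc) {
    do.call(rbind, lapply(seq_along(ks), function(i) {
      s <- survival_at(km[[oc]][[i]], horizons)
      data.frame(outcome = oc, cluster = ks[i], horizon = horizons,
                 survival_pct = round_half_up(100 * as.numeric(s), 1),
                 stringsAsFactors = FALSE)
    }))
  }))

  tests <- list()
  for (oc in binary_outcomes) {
    tab <- t(vapply(ks, function(cl) {
      c(events = sum(outcomes[[oc]][labels == cl]),
        nonevents = sum(labels == cl) - sum(outcomes[[oc]][labels == cl]))
    }, c(events = 0, nonevents = 0)))
    tr <- chi_squared_test(tab)
    tests[[oc]] <- data.frame(outcome = oc, test = tr$test_name,
                              statistic = tr$statistic, df = tr$df,
                              p_value = tr$p_value, stringsAsFactors = FALSE)
  }
  for (oc in names(tte_outcomes)) {
    groups <- lapply(ks, function(cl) {
      list(times = outcomes[[paste0(oc, "_time")]][labels == cl],
           events = outcomes[[paste0(oc, "_event")]][labels == cl])
    })
    tr <- logrank_test(groups)
    tests[[paste0(oc, "_survival")]] <- data.frame(
      outcome = paste0(oc, "_survival"), test = tr$test_name,
      statistic = tr$statistic, df = tr$df, p_value = tr$p_value,
      stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  tests$p_bonferroni <- pmin(1, tests$p_value * nrow(tests))

  structure(list(binary = binary, survival = surv, tests = tests, km = km,
                 horizons = horizons),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary>\n-- binary outcomes (count, %):\n")
  print(x$binary, row.names = FALSE)
  cat("-- survival (%) at years", paste(x$horizons, collapse = ", "), ":\n")
  print(x$survival, row.names = FALSE)
  cat("-- tests:\n")
  print(transform(x$tests, statistic = signif(statistic, 4),
                  p_value = signif(p_value, 3),
                  p_bonferroni = signif(p_bonferroni, 3)), row.names = FALSE)
  invisible(x)
}

#' Write the outcome summary and per-cluster KM curves as CSV
#'
#' @param summary An [outcome_summary()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_outcome_results <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary$binary, file.path(dir, "binary_outcomes.csv"), row.names = FALSE)
  utils::write.csv(summary$survival, file.path(dir, "survival_at_horizons.csv"), row.names = FALSE)
  utils::write.csv(summary$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  for (oc in names(summary$km)) {
    curves <- do.call(rbind, lapply(names(summary$km[[oc]]), function(cl) {
      f <- summary$km[[oc]][[cl]]
      if (length(f$event_times) == 0) return(NULL)
      data.frame(cluster = cl, time = f$event_times, survival = f$survival,
                 at_risk = f$at_risk, events = f$n_events,
                 greenwood_se = f$greenwood_se, stringsAsFactors = FALSE)
    }))
    if (!is.null(curves)) {
      utils::write.csv(curves, file.path(dir, paste0("km_", oc, ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}
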