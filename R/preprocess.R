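#' Cohort inclusion criteria
#'
#' Row filters applied before clustering: minimum donor KDPI percentile,
#' exclusion of simultaneous multi-organ transplants, and a transplant-year
#' window. A criterion is inactive (and its column not required) when
#' `kdpi_min = 0`, `exclude_multi_organ = FALSE`, or `year_range = NULL`.
#'
#' @param kdpi_min KDPI percentile threshold in `[0, 100]`; rows with
#'   `kdpi >= kdpi_min` are kept (default 85, the high-KDPI definition).
#' @param exclude_multi_organ Drop recipients of simultaneous multi-organ
#'   transplants (default TRUE).
#' @param year_range Inclusive transplant-year span, default `c(2010, 2019)`.
#' @return An object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(kdpi_min = 85, exclude_multi_organ = TRUE,
                               year_range = c(2010, 2019)) {
  if (kdpi_min < 0 || kdpi_min > 100) stop("kdpi_min must lie in [0, 100]", call. = FALSE)
  structure(list(kdpi_min = kdpi_min, exclude_multi_organ = exclude_multi_organ,
                 year_range = year_range),
            class = "inclusion_criteria")
}

#' Apply inclusion criteria to a cohort
#'
#' Keeps rows satisfying every active criterion, preserving row order. The
#' retained/dropped counts are attached as attribute `"inclusion_counts"` and
#' reported via [message()].
#'
#' @param cohort A [cohort_table()] carrying `kdpi`, `multi_organ`,
#'   `transplant_year` columns for whichever criteria are active.
#' @param criteria An [inclusion_criteria()].
#' @return Filtered `cohort_table`.
#' @export
apply_inclusion <- function(cohort, criteria = inclusion_criteria()) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(criteria, "inclusion_criteria"))
  n <- nrow(cohort$data)
  keep <- rep(TRUE, n)

  need <- function(col, why) {
    if (!col %in% names(cohort$data)) {
      stop("inclusion criterion '", why, "' requires column '", col, "'", call. = FALSE)
    }
    cohort$data[[col]]
  }
  if (criteria$kdpi_min > 0) {
    kdpi <- as.numeric(need("kdpi", "kdpi_min"))
    keep <- keep & !is.na(kdpi) & kdpi >= criteria$kdpi_min
  }
  if (isTRUE(criteria$exclude_multi_organ)) {
    mo <- need("multi_organ", "exclude_multi_organ")
    positive <- if (is.factor(mo)) mo == levels(mo)[2] else mo %in% c(1, TRUE, "yes")
    keep <- keep & !(positive %in% TRUE)
  }
  if (!is.null(criteria$year_range)) {
    yr <- need("transplant_year", "year_range")
    yr <- as.numeric(as.character(yr))
    keep <- keep & !is.na(yr) & yr >= criteria$year_range[1] & yr <= criteria$year_range[2]
  }

  out <- subset_cohort(cohort, keep)
  counts <- c(n_in = n, n_kept = sum(keep), n_dropped = sum(!keep))
  message("inclusion: kept ", counts["n_kept"], " of ", counts["n_in"], " subjects")
  attr(out, "inclusion_counts") <- counts
  out
}

#' Impute missing cohort cells by chained equations
#'
#' Produces a single completed dataset: missing cells are initialized by
#' random draws from the column's observed values, then refined over
#' `n_cycles` sweeps in which each incomplete variable is regressed on all
#' other variables using the current completed data — linear regression with
#' a residual-noise draw for continuous variables, a logistic draw for binary
#' variables, and a multinomial draw for categorical/ordinal variables.
#' Observed cells are never altered; the original `missing_mask` is retained
#' for audit. A variable whose model cannot be fit on a cycle falls back to a
#' draw from its observed values, with a warning.
#'
#' @param cohort A [cohort_table()].
#' @param n_cycles Number of chained sweeps (default 10).
#' @param seed Integer seed; the result is deterministic given data + seed.
#' @return Completed `cohort_table` (no NAs; mask unchanged).
#' @export
impute_chained <- function(cohort, n_cycles = 10, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"), n_cycles >= 1)
  mask <- cohort$missing_mask
  if (!any(mask)) return(cohort)
  fully_missing <- names(which(colSums(!mask) == 0))
  if (length(fully_missing)) {
    stop("column(s) fully missing, cannot impute: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  }

  set.seed(seed)
  data <- cohort$data
  incomplete <- names(which(colSums(mask) > 0))

  draw_observed <- function(v, n_draw) {
    obs <- data[[v]][!mask[, v]]
    obs[sample.int(length(obs), n_draw, replace = TRUE)]
  }
  for (v in incomplete) {
    data[[v]][mask[, v]] <- draw_observed(v, sum(mask[, v]))
  }

  for (cycle in seq_len(n_cycles)) {
    for (v in incomplete) {
      mis <- mask[, v]
      obs <- !mis
      kind <- cohort$schema[[v]]$kind
      others <- setdiff(names(data), v)
      X <- stats::model.matrix(~ ., data = data[others])
      imp <- tryCatch({
        if (kind == "continuous") {
          y <- data[[v]]
          fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          dfr <- max(sum(obs) - fit$rank, 1)
          sigma <- sqrt(sum(fit$residuals^2) / dfr)
          drop(X[mis, , drop = FALSE] %*% beta) + stats::rnorm(sum(mis), 0, sigma)
        } else if (kind == "binary") {
          y01 <- as.integer(data[[v]] == levels(data[[v]])[2])
          fit <- suppressWarnings(
            stats::glm.fit(X[obs, , drop = FALSE], y01[obs],
                           family = stats::binomial())
          )
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          p <- stats::plogis(drop(X[mis, , drop = FALSE] %*% beta))
          levels(data[[v]])[1 + (stats::runif(sum(mis)) < p)]
        } else {
          df <- as.data.frame(X[, -1, drop = FALSE])
          names(df) <- make.names(names(df), unique = TRUE)
          df$.y <- data[[v]]
          fit <- nnet::multinom(.y ~ ., data = df[obs, , drop = FALSE],
                                trace = FALSE, maxit = 200)
          p <- stats::predict(fit, newdata = df[mis, , drop = FALSE], type = "probs")
          p <- rbind(p)
          if (ncol(p) == 1) { # two observed classes collapse to one column
            p <- cbind(1 - p, p)
            colnames(p) <- fit$lev
          }
          apply(p, 1, function(pr) sample(colnames(p), 1, prob = pr))
        }
      }, error = function(e) {
        warning("imputation model for '", v, "' failed on cycle ", cycle,
                " (", conditionMessage(e), "); falling back to observed-value draw",
                call. = FALSE)
        draw_observed(v, sum(mis))
      })
      if (kind == "continuous") {
        data[[v]][mis] <- as.numeric(imp)
      } else {
        data[[v]][mis] <- factor(as.character(imp), levels = levels(data[[v]]),
                                 ordered = is.ordered(data[[v]]))
      }
    }
  }

  cohort$data <- data
  cohort
}

#' Column-mean / column-mode imputation (baseline comparator)
#'
#' Replaces each missing continuous cell by the column's observed mean and
#' each missing categorical cell by the observed modal level. Used as the
#' naive baseline against which chained-equation imputation is judged.
#'
#' @inheritParams impute_chained
#' @return Completed `cohort_table`.
#' @export
impute_column_mean <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  mask <- cohort$missing_mask
  data <- cohort$data
  for (v in names(which(colSums(mask) > 0))) {
    mis <- mask[, v]
    if (cohort$schema[[v]]$kind == "continuous") {
      data[[v]][mis] <- mean(data[[v]][!mis])
    } else {
      tab <- table(data[[v]][!mis])
      data[[v]][mis] <- names(tab)[which.max(tab)]
    }
  }
  cohort$data <- data
  cohort
}

#' Mixed-type pairwise dissimilarity
#'
#' Gower dissimilarity (the default): continuous and ordinal variables
#' contribute `|x_i - x_j| / range` (ordinal via integer level ranks), binary
#' and categorical variables contribute 0 if equal else 1; the distance is
#' the unweighted mean contribution over the variables used. Variables with
#' zero observed range contribute 0 and are reported in a warning. The
#' alternative `"onehot_euclidean"` metric min-max scales continuous/ordinal
#' columns, one-hot encodes categorical levels, and normalizes the Euclidean
#' distance to `[0, 1]` — offered for sensitivity analysis.
#'
#' @param cohort A complete [cohort_table()] (run [impute_chained()] first).
#' @param vars Columns to use; default all non-admin schema columns.
#' @param method `"gower"` (default) or `"onehot_euclidean"`.
#' @return An object of class `distance_matrix`: list with `values`
#'   (symmetric n x n matrix, zero diagonal, entries in `[0, 1]`) and
#'   `subject_id` in cohort order.
#' @export
gower_distance <- function(cohort, vars = NULL,
                           method = c("gower", "onehot_euclidean")) {
  stopifnot(inherits(cohort, "cohort_table"))
  method <- match.arg(method)
  if (is.null(vars)) vars <- setdiff(names(cohort$data), cohort$admin_vars)
  data <- cohort$data[vars]
  if (anyNA(data)) {
    stop("cohort has missing cells; run impute_chained() before gower_distance()",
         call. = FALSE)
  }
  n <- nrow(data)
  kinds <- vapply(cohort$schema[vars], `[[`, "", "kind")

  numeric_code <- function(v, kind) {
    if (kind == "continuous") as.numeric(data[[v]]) else as.numeric(data[[v]])
  }

  if (method == "gower") {
    D <- matrix(0, n, n)
    zero_range <- character()
    for (v in vars) {
      kind <- kinds[[v]]
      if (kind %in% c("continuous", "ordinal")) {
        x <- as.numeric(data[[v]]) # ordinal factors -> integer level ranks
        rng <- max(x) - min(x)
        if (rng == 0) { zero_range <- c(zero_range, v); next }
        D <- D + abs(outer(x, x, "-")) / rng
      } else {
        x <- as.integer(data[[v]])
        if (length(unique(x)) == 1) { zero_range <- c(zero_range, v); next }
        D <- D + (outer(x, x, "!=") + 0)
      }
    }
    if (length(zero_range)) {
      warning("zero-range variable(s) contribute no distance: ",
              paste(zero_range, collapse = ", "), call. = FALSE)
    }
    D <- D / length(vars)
  } else {
    cols <- list()
    for (v in vars) {
      kind <- kinds[[v]]
      if (kind %in% c("continuous", "ordinal")) {
        x <- as.numeric(data[[v]])
        rng <- max(x) - min(x)
        cols[[v]] <- if (rng == 0) rep(0, n) else (x - min(x)) / rng
      } else {
        f <- data[[v]]
        for (lv in levels(f)) cols[[paste0(v, "=", lv)]] <- as.numeric(f == lv)
      }
    }
    M <- do.call(cbind, cols)
    # max possible squared distance: 1 per scaled column, 2 per categorical
    max_sq <- sum(kinds %in% c("continuous", "ordinal")) +
      2 * sum(!(kinds %in% c("continuous", "ordinal")))
    D <- as.matrix(stats::dist(M)) / sqrt(max_sq)
  }

  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(cohort$subject_id, cohort$subject_id)
  structure(list(values = D, subject_id = cohort$subject_id),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix>", nrow(x$values), "subjects; range [",
      round(min(x$values), 4), ",", round(max(x$values), 4), "]\n")
  invisible(x)
}

#' Write / read a dense distance matrix as CSV (header = subject IDs)
#' @param dist A `distance_matrix`.
#' @param path CSV path.
#' @return `read_distance` returns a `distance_matrix`; `write_distance`
#'   returns `path` invisibly.
#' @export
write_distance <- function(dist, path) {
  utils::write.csv(as.data.frame(dist$values), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  ids <- colnames(m)
  dimnames(m) <- list(ids, ids)
  structure(list(values = m, subject_id = ids), class = "distance_matrix")
}
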