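#' Declare one cohort variable
#'
#' A variable specification records the measurement kind of a cohort column
#' and, for the synthetic generator, its per-cluster distribution parameters.
#'
#' @param name Column name.
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`, `"ordinal"`.
#' @param levels Character vector of category labels (non-continuous kinds).
#'   Binary variables default to `c("no", "yes")`; ordinal levels are in
#'   increasing order.
#' @param mean,sd Per-cluster means and standard deviations (continuous only);
#'   recycled to the number of clusters. All `sd` must be > 0.
#' @param prob For binary variables a per-cluster probability of the second
#'   ("yes") level; for categorical/ordinal a clusters x levels matrix (or a
#'   single probability vector recycled across clusters) whose rows sum to 1.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind = c("continuous", "binary", "categorical", "ordinal"),
                          levels = NULL, mean = NULL, sd = NULL, prob = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (is.null(mean) || is.null(sd)) {
      stop("continuous variable '", name, "' needs mean and sd", call. = FALSE)
    }
    if (any(sd <= 0)) stop("variable '", name, "': sd must be > 0", call. = FALSE)
    levels <- NULL
  } else {
    if (kind == "binary" && is.null(levels)) levels <- c("no", "yes")
    if (is.null(levels) || length(levels) < 2) {
      stop("variable '", name, "' needs >= 2 levels", call. = FALSE)
    }
    if (kind == "binary") {
      if (length(levels) != 2) stop("binary variable '", name, "' needs exactly 2 levels", call. = FALSE)
      if (!is.null(prob)) prob <- cbind(1 - prob, prob)
    }
    if (!is.null(prob)) {
      prob <- rbind(prob)
      if (ncol(prob) != length(levels)) {
        stop("variable '", name, "': prob columns must match levels", call. = FALSE)
      }
      if (any(abs(rowSums(prob) - 1) > 1e-9)) {
        stop("variable '", name, "': level probabilities must sum to 1", call. = FALSE)
      }
    }
  }
  structure(
    list(name = name, kind = kind, levels = levels,
         mean = mean, sd = sd, prob = prob),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat("<variable_spec>", x$name, "(", x$kind, ")\n")
  if (!is.null(x$levels)) cat("  levels:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

# schema = named list of kind/levels per column (no generator parameters)
schema_from_specs <- function(specs) {
  out <- lapply(specs, function(s) list(kind = s$kind, levels = s$levels))
  names(out) <- vapply(specs, `[[`, "", "name")
  out
}

#' Write / read a variable schema as JSON
#'
#' The schema is a named list, one entry per cohort column, with fields
#' `kind` and (for non-continuous kinds) `levels`.
#'
#' @param schema Named list as stored in a [cohort_table()].
#' @param path File path.
#' @return `read_schema` returns the schema list; `write_schema` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(schema, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(e) {
    list(kind = e$kind,
         levels = if (!is.null(e$levels)) unlist(e$levels) else NULL)
  })
}
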