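#' Cohort table: subjects x mixed-type variables with a schema
#'
#' The analysis substrate: one row per transplant recipient, columns of
#' declared kinds (continuous, binary, categorical, ordinal), a missingness
#' mask, and unique subject identifiers. Categorical/binary/ordinal columns
#' are stored as factors with the schema's level set (ordinal as ordered
#' factors); continuous columns as numeric.
#'
#' @param data A data.frame of cohort variables (no ID column).
#' @param schema Named list with one entry per column: `list(kind =, levels =)`.
#' @param subject_id Unique identifiers, one per row. Default `"S1"..."Sn"`.
#' @param admin_vars Columns carried for filtering/bookkeeping (for example
#'   `multi_organ`, `transplant_year`) that distance computations skip by
#'   default.
#' @return An object of class `cohort_table` with fields `data`, `schema`,
#'   `subject_id`, `missing_mask` (logical, TRUE = missing), `admin_vars`.
#' @export
cohort_table <- function(data, schema, subject_id = NULL, admin_vars = character()) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(subject_id)) subject_id <- paste0("S", seq_len(nrow(data)))
  if (anyDuplicated(subject_id)) stop("subject_id values must be unique", call. = FALSE)
  if (length(subject_id) != nrow(data)) stop("subject_id length must match rows", call. = FALSE)

  missing_cols <- setdiff(names(data), names(schema))
  if (length(missing_cols)) {
    stop("columns absent from schema: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[names(schema)[names(schema) %in% names(data)]]
  for (v in names(data)) {
    kind <- schema[[v]]$kind
    if (kind == "continuous") {
      data[[v]] <- as.numeric(data[[v]])
    } else {
      lv <- schema[[v]]$levels
      vals <- as.character(data[[v]])
      bad <- !is.na(vals) & !(vals %in% lv)
      if (any(bad)) {
        stop("column '", v, "' has values outside declared levels: ",
             paste(unique(vals[bad]), collapse = ", "), call. = FALSE)
      }
      data[[v]] <- factor(vals, levels = lv, ordered = (kind == "ordinal"))
    }
  }
  mask <- is.na(as.matrix(data))
  dimnames(mask) <- list(NULL, names(data))

  frac <- colMeans(mask)
  high <- frac[frac >= 0.05]
  if (length(high)) {
    warning("per-column missingness >= 5%: ",
            paste0(names(high), " (", round(100 * frac[names(high)], 1), "%)",
                   collapse = ", "), call. = FALSE)
  }

  structure(
    list(data = data, schema = schema[names(data)], subject_id = subject_id,
         missing_mask = mask, admin_vars = intersect(admin_vars, names(data))),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  kinds <- vapply(x$schema, `[[`, "", "kind")
  cat("<cohort_table> ", nrow(x$data), " subjects x ", ncol(x$data), " variables (",
      sum(kinds == "continuous"), " continuous, ",
      sum(kinds == "binary"), " binary, ",
      sum(kinds == "categorical"), " categorical, ",
      sum(kinds == "ordinal"), " ordinal)\n", sep = "")
  nm <- sum(x$missing_mask)
  cat("  missing cells: ", nm, " (", round(100 * mean(x$missing_mask), 2), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

# row subset preserving class and mask
subset_cohort <- function(cohort, keep) {
  out <- cohort
  out$data <- cohort$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out$subject_id <- cohort$subject_id[keep]
  out$missing_mask <- cohort$missing_mask[keep, , drop = FALSE]
  out
}

#' Read / write a cohort as CSV plus schema JSON
#'
#' The CSV has `subject_id` as its first column; factor levels and variable
#' kinds travel in the companion schema file.
#'
#' @param cohort A [cohort_table()].
#' @param path CSV path.
#' @param schema_path Schema JSON path; defaults to `path` with a `.json`
#'   extension.
#' @param admin_vars Passed to [cohort_table()] on read.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path, schema_path = sub("\\.csv$", ".json", path)) {
  out <- data.frame(subject_id = cohort$subject_id, cohort$data,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  write_schema(cohort$schema, schema_path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema_path = sub("\\.csv$", ".json", path),
                        admin_vars = character()) {
  schema <- read_schema(schema_path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         check.names = FALSE, colClasses = "character")
  if (!"subject_id" %in% names(raw)) stop("cohort CSV must carry a subject_id column", call. = FALSE)
  ids <- raw$subject_id
  raw$subject_id <- NULL
  cohort_table(raw, schema, subject_id = ids, admin_vars = admin_vars)
}
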