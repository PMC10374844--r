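#' Construct a cohort table
#'
#' A cohort table couples a patient-by-feature data.frame with its feature
#' schema. Rows are patients; columns are `patient_id`, the schema features
#' (in schema order), the binary `outcome` (1 = rare class, i.e. occult
#' adnexal tumor at RRSO; 0 = abundant class / control) and an optional
#' `subtype` (`"STIC"`, `"invasive"` or `"none"`).
#'
#' Feature values may be missing (`NA`); the outcome may not. Binary features
#' must lie in \{0, 1\}, counts must be non-negative integers, continuous
#' values must be finite.
#'
#' @param data data.frame with the columns described above.
#' @param schema A `feature_schema`, see [default_schema()].
#' @return An object of class `cohort_table` with elements `data` and
#'   `schema`.
#' @export
cohort_table <- function(data, schema = default_schema()) {
  validate_cohort_data(data, schema)
  cols <- c("patient_id", schema$name, "outcome",
            if ("subtype" %in% names(data)) "subtype")
  data <- data[, cols, drop = FALSE]
  data$patient_id <- as.character(data$patient_id)
  rownames(data) <- NULL
  structure(list(data = data, schema = schema), class = "cohort_table")
}

validate_cohort_data <- function(data, schema) {
  if (!is.data.frame(data)) stop("cohort data must be a data.frame")
  if (nrow(data) == 0) stop("cohort table has no patients (0 data rows)")
  needed <- c("patient_id", schema$name, "outcome")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) {
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  }
  unknown <- setdiff(names(data), c(needed, "subtype"))
  if (length(unknown) > 0) {
    stop("unknown column(s) not in schema: ", paste(unknown, collapse = ", "))
  }
  if (anyNA(data$outcome)) {
    stop("outcome must never be missing (rows: ",
         paste(which(is.na(data$outcome)), collapse = ", "), ")")
  }
  if (!all(data$outcome %in% c(0, 1))) {
    stop("outcome must be 0 (abundant class) or 1 (rare class)")
  }
  kinds <- feature_kinds(schema)
  for (f in schema$name) {
    x <- data[[f]]
    if (!is.numeric(x) && !all(is.na(x))) {
      stop("feature '", f, "' must be numeric")
    }
    obs <- which(!is.na(x))
    if (length(obs) == 0) next
    v <- x[obs]
    bad <- switch(kinds[[f]],
      binary     = obs[!(v %in% c(0, 1))],
      count      = obs[!(is.finite(v) & v >= 0 & v == round(v))],
      continuous = obs[!is.finite(v)]
    )
    if (length(bad) > 0) {
      stop("invalid ", kinds[[f]], " value in column '", f, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_table <- function(x, ...) {
  n1 <- sum(x$data$outcome == 1)
  cat(sprintf("cohort_table: %d patients x %d features; %d rare-class (%.1f%%)\n",
              nrow(x$data), nrow(x$schema), n1, 100 * n1 / nrow(x$data)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param table A `cohort_table`.
#' @return Integer patient count.
#' @export
n_patients <- function(table) nrow(table$data)

#' Extract the numeric feature matrix of a cohort
#'
#' @param table A `cohort_table`.
#' @return Numeric matrix (patients x features) in schema column order, with
#'   `patient_id` as rownames. Missing values propagate as `NA`.
#' @export
cohort_matrix <- function(table) {
  m <- as.matrix(table$data[, table$schema$name, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$data$patient_id
  m
}
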