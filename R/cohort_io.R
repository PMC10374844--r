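#' Read a cohort CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and one patient per
#' row: columns `patient_id`, the 20 schema features, `outcome` and optionally
#' `subtype`. Missing feature values are encoded as an empty cell or the
#' literal `NA` (case-insensitive); nothing else is silently coerced.
#'
#' @param path File path.
#' @param schema A `feature_schema`; defaults to the packaged schema.
#' @return A validated [cohort_table()], rows in file order.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop("cohort file '", path, "' has no data rows")
  for (f in schema$name) {
    if (!f %in% names(df)) next
    x <- trimws(df[[f]])
    x[x == "" | toupper(x) == "NA"] <- NA_character_
    bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad) > 0) {
      stop("non-numeric value '", x[bad[1]], "' in column '", f,
           "' at row ", bad[1])
    }
    df[[f]] <- as.numeric(x)
  }
  if ("outcome" %in% names(df)) {
    df$outcome <- as.numeric(df$outcome)
  }
  cohort_table(df, schema)
}

#' Write a cohort CSV
#'
#' Columns are written in fixed schema order so outputs are diffable; missing
#' values become empty cells; continuous values are rounded to 6 decimals.
#'
#' @param table A `cohort_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path) {
  if (!inherits(table, "cohort_table")) stop("not a cohort_table")
  if (nrow(table$schema) == 0) stop("cohort has an empty feature set")
  df <- table$data
  kinds <- feature_kinds(table$schema)
  for (f in table$schema$name) {
    if (kinds[[f]] == "continuous") df[[f]] <- round(df[[f]], 6)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Summarize a cohort in the clinical-table format
#'
#' Continuous and count features are summarized by the median and first/third
#' quartiles (linear-interpolation quantiles over observed values); binary
#' features by Yes/No absolute counts and percentages. Missing counts and
#' percentages are reported per feature; percentages are computed against the
#' total cohort size and rounded to 1 decimal.
#'
#' @param table A `cohort_table`.
#' @return A data.frame of class `cohort_summary` with one row per feature:
#'   `feature, kind, median, q1, q3, n_yes, n_no, pct_yes, pct_no, n_missing,
#'   pct_missing`.
#' @export
summarize_cohort <- function(table) {
  if (!inherits(table, "cohort_table")) stop("not a cohort_table")
  n <- n_patients(table)
  kinds <- feature_kinds(table$schema)
  rows <- lapply(table$schema$name, function(f) {
    x <- table$data[[f]]
    nmiss <- sum(is.na(x))
    obs <- x[!is.na(x)]
    out <- data.frame(feature = f, kind = kinds[[f]],
                      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                      n_yes = NA_integer_, n_no = NA_integer_,
                      pct_yes = NA_real_, pct_no = NA_real_,
                      n_missing = nmiss,
                      pct_missing = round(100 * nmiss / n, 1))
    if (length(obs) == 0) return(out)  # fully missing: NA summary, no crash
    if (kinds[[f]] == "binary") {
      out$n_yes <- sum(obs == 1)
      out$n_no <- sum(obs == 0)
      out$pct_yes <- round(100 * out$n_yes / n, 1)
      out$pct_no <- round(100 * out$n_no / n, 1)
    } else {
      q <- stats::quantile(obs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out$q1 <- q[1]; out$median <- q[2]; out$q3 <- q[3]
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("cohort_summary", "data.frame")
  res
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    if (x$kind[i] == "binary") {
      cat(sprintf("%-18s No %3d; %4.1f%%  Yes %3d; %4.1f%%  NA %d; %.1f%%\n",
                  x$feature[i], x$n_no[i], x$pct_no[i], x$n_yes[i],
                  x$pct_yes[i], x$n_missing[i], x$pct_missing[i]))
    } else {
      cat(sprintf("%-18s median %g [%g, %g]  NA %d; %.1f%%\n",
                  x$feature[i], x$median[i], x$q1[i], x$q3[i],
                  x$n_missing[i], x$pct_missing[i]))
    }
  }
  invisible(x)
}
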