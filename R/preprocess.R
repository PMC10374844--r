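#' Proximity imputation of missing values
#'
#' For each patient with missing features, the donor is the fully-observed
#' patient whose feature vector — restricted to exactly the features the
#' recipient has observed — minimizes the Euclidean distance to the
#' recipient's. The recipient receives the donor's values for each of its
#' missing features, so imputed values always come from the observed support.
#' Distances are computed on raw (unstandardized) values, since imputation
#' precedes standardization in the pipeline. Equidistant donors are broken
#' deterministically toward the lowest row index, and the tie is recorded.
#'
#' @param table A `cohort_table`.
#' @return A list with elements:
#'   * `table` — the completed `cohort_table`;
#'   * `records` — data.frame of class `imputation_record` with one row per
#'     imputed cell: `patient_id, feature, donor_id, distance, tie`.
#' @export
impute_missing <- function(table) {
  if (!inherits(table, "cohort_table")) stop("not a cohort_table")
  X <- cohort_matrix(table)
  incomplete <- which(rowSums(is.na(X)) > 0)
  empty_rec <- data.frame(patient_id = character(), feature = character(),
                          donor_id = character(), distance = numeric(),
                          tie = logical())
  if (length(incomplete) == 0) {
    return(list(table = table, records = empty_rec))
  }
  donors <- which(rowSums(is.na(X)) == 0)
  if (length(donors) == 0) {
    stop("proximity imputation needs at least one fully-observed patient; ",
         "relax the schema or pre-fill some values")
  }
  D <- X[donors, , drop = FALSE]
  recs <- vector("list", length(incomplete))
  out <- table$data
  for (j in seq_along(incomplete)) {
    i <- incomplete[j]
    obs <- which(!is.na(X[i, ]))
    if (length(obs) > 0) {
      delta <- sweep(D[, obs, drop = FALSE], 2, X[i, obs], "-")
      d <- sqrt(rowSums(delta^2))
    } else {
      d <- rep(0, nrow(D))  # nothing observed: every donor is equidistant
    }
    best <- which.min(d)  # lowest row index on ties
    tie <- sum(abs(d - d[best]) < 1e-12) > 1
    miss <- which(is.na(X[i, ]))
    for (f in colnames(X)[miss]) {
      out[i, f] <- table$data[donors[best], f]
    }
    recs[[j]] <- data.frame(patient_id = table$data$patient_id[i],
                            feature = colnames(X)[miss],
                            donor_id = table$data$patient_id[donors[best]],
                            distance = unname(d[best]), tie = tie)
  }
  records <- do.call(rbind, recs)
  class(records) <- c("imputation_record", "data.frame")
  list(table = cohort_table(out, table$schema), records = records)
}

#' Standardize continuous features
#'
#' Removes the mean and scales to unit variance (population variance,
#' denominator n) every feature of kind `continuous`; binary and count
#' features are left untouched. With `params = NULL` the statistics are
#' computed on `table` itself (self-fit mode); supplying previously computed
#' params applies them unchanged — this is the leakage-safe train-only mode,
#' where params fitted on a training set are applied to held-out patients.
#'
#' @param table A complete (post-imputation) `cohort_table`.
#' @param params Optional `standardization_params` from a previous call.
#' @return A list with elements `table` (transformed) and `params`
#'   (data.frame of class `standardization_params`: `feature, mean, sd`).
#' @export
standardize <- function(table, params = NULL) {
  if (!inherits(table, "cohort_table")) stop("not a cohort_table")
  cont <- table$schema$name[table$schema$kind == "continuous"]
  if (is.null(params)) {
    stats_list <- lapply(cont, function(f) {
      x <- table$data[[f]]
      if (anyNA(x)) stop("standardize requires a complete table; feature '",
                         f, "' has missing values (impute first)")
      mu <- mean(x)
      sd_pop <- sqrt(mean((x - mu)^2))
      if (sd_pop == 0) stop("feature '", f, "' has zero variance")
      data.frame(feature = f, mean = mu, sd = sd_pop)
    })
    params <- do.call(rbind, stats_list)
    class(params) <- c("standardization_params", "data.frame")
  } else {
    if (!all(cont %in% params$feature)) {
      stop("params do not cover every continuous feature")
    }
    if (any(params$sd <= 0)) stop("standardization params must have sd > 0")
  }
  out <- table$data
  for (k in seq_len(nrow(params))) {
    f <- params$feature[k]
    out[[f]] <- (out[[f]] - params$mean[k]) / params$sd[k]
  }
  list(table = cohort_table(out, table$schema), params = params)
}

#' Invert a standardization
#'
#' @param table A standardized `cohort_table`.
#' @param params The `standardization_params` used to standardize it.
#' @return The `cohort_table` on the original scale.
#' @export
destandardize <- function(table, params) {
  out <- table$data
  for (k in seq_len(nrow(params))) {
    f <- params$feature[k]
    out[[f]] <- out[[f]] * params$sd[k] + params$mean[k]
  }
  cohort_table(out, table$schema)
}
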