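#' Clinical feature schema
#'
#' The default schema describes the 20 clinical variables collected before
#' risk-reducing salpingo-oophorectomy (RRSO): patient age and BMI, age of
#' menarche, BRCA1/BRCA2 mutation status, preoperative serum CA-125,
#' menopause at time of RRSO, number of full-term pregnancies, estroprogestin
#' use, history of endometriosis, previous abdominal/pelvic surgery, previous
#' breast cancer, and breast/ovarian cancer status and counts among first- and
#' second-degree relatives.
#'
#' Each feature has a `kind` that drives validation, the synthetic generator
#' and the univariate test used downstream:
#' * `continuous` — finite real values; standardized before modelling and
#'   compared between classes by the rank-sum test.
#' * `binary` — 0/1; compared by the chi-square test.
#' * `count` — non-negative integers; compared by the rank-sum test.
#'
#' @param path Optional path to a schema CSV with columns
#'   `name, display_name, kind, unit`. Defaults to the packaged schema.
#' @return A data.frame of class `feature_schema` with one row per feature.
#' @export
#' @examples
#' s <- default_schema()
#' table(s$kind)
default_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "clinical_schema.csv", package = "rrsorisk")
  }
  s <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
  read_schema(s)
}

#' Build a feature schema from a data.frame
#'
#' @param s data.frame with columns `name`, `display_name`, `kind`, `unit`.
#' @return A validated `feature_schema`.
#' @export
read_schema <- function(s) {
  required <- c("name", "display_name", "kind", "unit")
  missing_cols <- setdiff(required, names(s))
  if (length(missing_cols) > 0) {
    stop("schema is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(s$name)) {
    stop("schema feature names must be unique")
  }
  bad <- setdiff(unique(s$kind), c("continuous", "binary", "count"))
  if (length(bad) > 0) {
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  }
  s <- s[, required]
  class(s) <- c("feature_schema", "data.frame")
  s
}

feature_kinds <- function(schema) {
  stats::setNames(schema$kind, schema$name)
}
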