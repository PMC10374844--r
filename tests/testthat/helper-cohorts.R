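# Small fixtures built in code: a 4-feature schema and cohort builders used
# across the module tests.

mini_schema <- function() {
  read_schema(data.frame(
    name = c("Age", "BMI", "PAPS", "Nrel"),
    display_name = c("Age", "BMI", "PAPS", "N relatives"),
    kind = c("continuous", "continuous", "binary", "count"),
    unit = c("years", "kg/m2", "", "")))
}

# Hand-built cohort over the mini schema.
mini_cohort <- function(age, bmi, paps = NULL, nrel = NULL, outcome = NULL) {
  n <- length(age)
  cohort_table(data.frame(
    patient_id = paste0("P", seq_len(n)),
    Age = age, BMI = bmi,
    PAPS = paps %||% rep(0, n),
    Nrel = nrel %||% rep(0, n),
    outcome = outcome %||% rep(c(1, 0), length.out = n)),
    mini_schema())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Generator config over the mini schema; effects optional.
mini_gen_config <- function(n = 24, n_rare = 6, effects = NULL, seed = 1) {
  generator_config(
    n_patients = n, n_rare = n_rare, n_stic = 0,
    marginals = list(
      Age  = list(kind = "continuous", q1 = 45, median = 50, q3 = 56, lower = 18),
      BMI  = list(kind = "continuous", q1 = 22, median = 24.2, q3 = 27.2, lower = 14),
      PAPS = list(kind = "binary", prob = 0.4),
      Nrel = list(kind = "count", probs = c(0.6, 0.3, 0.08, 0.02))),
    missingness = integer(), effects = effects, seed = seed,
    schema = mini_schema())
}

# Separable-by-construction training data in 1 dimension plus noise columns.
separable_xy <- function(n_per_class = 10, gap = 4, p_noise = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(stats::rnorm(n * (1 + p_noise)), n, 1 + p_noise)
  colnames(X) <- c("signal", paste0("noise", seq_len(p_noise), recycle0 = TRUE))
  y <- rep(c(1, 0), each = n_per_class)
  X[, "signal"] <- stats::rnorm(n, mean = ifelse(y == 1, gap / 2, -gap / 2),
                                sd = 0.5)
  list(X = X, y = y)
}
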