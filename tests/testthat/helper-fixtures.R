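# Worked-example fixtures and random-table generators shared by the suite.

# Seven-person income table: two missing incomes, observed values
# 100, 100, 300, 200, 200 (mean 180).
income_table <- function() {
  sch <- schema(
    variable_spec("Gender", "binary", c("Female", "Male")),
    variable_spec("Income", "numeric")
  )
  sice_table(data.frame(
    Gender = c("Female", "Female", "Male", "Female", "Male", "Male", "Female"),
    Income = c(100, NA, 100, 300, NA, 200, 200),
    stringsAsFactors = FALSE
  ), sch)
}

# Ten-patient mortality table: three missing death reasons, observed mode
# "Cancer".
death_reason_table <- function() {
  sch <- schema(
    variable_spec("Age", "numeric"),
    variable_spec("DeathReason", "nominal",
                  c("Covid-19", "Heart attack", "Cancer"))
  )
  sice_table(data.frame(
    Age = c(60, 64, 42, 67, 80, 32, 35, 45, 88, 33),
    DeathReason = c("Covid-19", NA, "Heart attack", "Covid-19", NA, "Cancer",
                    "Cancer", "Cancer", NA, "Heart attack"),
    stringsAsFactors = FALSE
  ), sch)
}

# Random mixed-type table with missing cells, for property tests.
random_table <- function(n = 12L, na_frac = 0.2) {
  sch <- schema(
    variable_spec("b", "binary", c("no", "yes")),
    variable_spec("n", "nominal", c("x", "y", "z")),
    variable_spec("o", "ordinal", c("low", "mid", "high")),
    variable_spec("v", "numeric")
  )
  df <- data.frame(
    b = sample(c("no", "yes"), n, replace = TRUE),
    n = sample(c("x", "y", "z"), n, replace = TRUE),
    o = sample(c("low", "mid", "high"), n, replace = TRUE),
    v = round(stats::rnorm(n, 50, 10), 3),
    stringsAsFactors = FALSE
  )
  for (cn in names(df)) {
    hit <- stats::runif(n) < na_frac
    df[[cn]][hit] <- NA
  }
  sice_table(df, sch)
}

# Single numeric column 1..n, used for amputation count checks.
serial_table <- function(n) {
  sch <- schema(variable_spec("v", "numeric"))
  sice_table(data.frame(v = as.numeric(seq_len(n))), sch)
}

# Two-column numeric task: target k regressed on predictor l.
numeric_task <- function(l, k, mask = is.na(k)) {
  sch <- schema(variable_spec("l", "numeric"), variable_spec("k", "numeric"))
  tab <- sice_table(data.frame(l = l, k = k), sch)
  impute_task(tab, "k", mask = mask)
}

# Categorical target g over one numeric predictor x.
class_task <- function(x, g, levels, vartype = "nominal", mask = is.na(g)) {
  sch <- schema(variable_spec("x", "numeric"),
                variable_spec("g", vartype, levels))
  tab <- sice_table(data.frame(x = x, g = g, stringsAsFactors = FALSE), sch)
  impute_task(tab, "g", mask = mask)
}

# Build an imputation stack by hand for pooling tests.
manual_stack <- function(rows, columns, values, m = length(values[[1L]])) {
  structure(list(m = m,
                 cells = data.frame(row = rows, column = columns,
                                    stringsAsFactors = FALSE),
                 values = values),
            class = "sice_stack")
}

# Exhaustive-search oracle for the first CART split: maximal achievable
# impurity gain over all (numeric column, threshold) candidates honoring the
# minimum leaf size.
split_gain <- function(y, left, numeric_y) {
  imp <- if (numeric_y) {
    function(v) sum((v - mean(v))^2)
  } else {
    function(v) { p <- table(v) / length(v); length(v) * (1 - sum(p^2)) }
  }
  imp(y) - imp(y[left]) - imp(y[!left])
}

oracle_best_gain <- function(df, y, min_leaf, numeric_y) {
  best <- -Inf
  for (cn in names(df)) {
    u <- sort(unique(df[[cn]]))
    if (length(u) < 2L) next
    for (thr in utils::head(u, -1L) + diff(u) / 2) {
      left <- df[[cn]] < thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      best <- max(best, split_gain(y, left, numeric_y))
    }
  }
  best
}
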