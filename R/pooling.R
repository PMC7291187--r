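# Mode of one stacked cell with the documented deterministic tie-break:
# highest stack frequency; ties toward the level more frequent among the
# column's observed values; remaining ties toward earlier schema level order.
pool_mode <- function(vals, observed_counts, levels) {
  counts <- table(factor(vals, levels = levels))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  obs <- observed_counts[top]
  top <- top[obs == max(obs)]
  top[1L]                                  # earlier schema level wins
}

pool_stack <- function(stack, table, allowed) {
  sch <- table_schema(table)
  if (nrow(stack$cells) == 0L) return(table)
  types <- vapply(unique(stack$cells$column), function(cn)
    vartype_of(sch, cn), character(1))
  bad <- types[!types %in% allowed]
  if (length(bad)) {
    stop("stacked column of type ", bad[1L], " cannot be pooled by this rule",
         call. = FALSE)
  }
  out <- table
  obs_counts <- lapply(sch, function(v) {
    if (is_categorical(v$vartype)) {
      table(factor(as.character(table[[v$name]]), levels = v$levels))
    }
  })
  for (i in seq_len(nrow(stack$cells))) {
    r <- stack$cells$row[i]; cn <- stack$cells$column[i]
    vals <- stack$values[[i]]
    if (length(vals) == 0L) {
      stop("empty imputation array at (row ", r, ", \"", cn,
           "\"): engine contract violated", call. = FALSE)
    }
    if (sch[[cn]]$vartype == "numeric") {
      if (!is.numeric(vals)) {
        stop("non-numeric value in the array of numeric cell (row ", r,
             ", \"", cn, "\")", call. = FALSE)
      }
      out[[cn]][r] <- mean(vals)
    } else {
      out[[cn]][r] <- pool_mode(as.character(vals), obs_counts[[cn]],
                                sch[[cn]]$levels)
    }
  }
  out
}

#' Collapse a categorical imputation stack by majority vote
#'
#' The categorical pooling rule: every missing cell receives the most
#' frequent value of its m-length imputation array. Ties are broken
#' deterministically — first toward the level with the higher frequency
#' among the column's observed values, then toward the earlier schema level
#' — so pooling never consumes randomness. Observed cells are untouched.
#'
#' @param stack A `sice_stack` whose columns are all categorical.
#' @param table The original incomplete `sice_table`.
#' @return A completed `sice_table`.
#' @export
sice_categorical <- function(stack, table) {
  pool_stack(stack, table, allowed = c("binary", "nominal", "ordinal"))
}

#' Collapse a numeric imputation stack by the arithmetic mean
#'
#' The numeric pooling rule: every missing cell receives the mean of its
#' m-length imputation array (not rounded to an observed value). With m = 1
#' this reduces to the single chain's draw. Observed cells are untouched.
#'
#' @param stack A `sice_stack` whose columns are all numeric.
#' @param table The original incomplete `sice_table`.
#' @return A completed `sice_table`.
#' @export
sice_numeric <- function(stack, table) {
  pool_stack(stack, table, allowed = "numeric")
}

#' Pool a mixed stack, choosing the rule per column type
#'
#' Applies the mean rule to numeric columns and the majority rule to
#' categorical columns of the same stack.
#'
#' @param stack A `sice_stack`.
#' @param table The original incomplete `sice_table`.
#' @return A completed `sice_table`.
#' @export
sice_pool <- function(stack, table) {
  pool_stack(stack, table, allowed = c("binary", "nominal", "ordinal", "numeric"))
}

#' One-call hybrid imputation: chained engine plus pooling
#'
#' Runs [run_mice()], stacks the m candidate values of every missing cell,
#' and collapses the stack with [sice_pool()], returning one completed
#' dataset instead of m.
#'
#' @param table An incomplete `sice_table`.
#' @param spec A [chain_spec()].
#' @return A completed `sice_table`.
#' @examples
#' tab <- generate_health_like(n_rows = 200, seed = 1)
#' amp <- ampute_mcar(tab, "Age", rate = 0.1, seed = 2)
#' done <- sice_impute(amp$table, chain_spec(m = 7, seed = 3))
#' anyNA(done$Age)
#' @export
sice_impute <- function(table, spec) {
  completed <- run_mice(table, spec)
  sice_pool(collect_stack(completed, table), table)
}
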