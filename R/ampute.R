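# Run code under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Mask a fraction of a fully observed column, keeping ground truth
#'
#' Implements MCAR amputation for benchmarking: exactly
#' `floor(rate * n_rows)` cells of the target column are set to missing,
#' chosen uniformly at random without replacement, independent of every value
#' in the table. The removed values are retained so the imputation can later
#' be scored against them, and the mask is deterministic given the seed.
#'
#' @param table A `sice_table` whose `target` column has no missing cells.
#' @param target Column name to ampute.
#' @param rate Fraction of rows to mask, in `[0, 1)`.
#' @param seed Integer seed; the same seed always yields the same mask.
#' @return An object of class `sice_amputed`: a list with elements
#'   `table` (the amputed `sice_table`), `target`, `mask` (logical vector,
#'   `TRUE` = artificially masked), and `truth` (data.frame with columns
#'   `row` and `original_value`).
#' @examples
#' tab <- generate_health_like(n_rows = 100, seed = 1)
#' amp <- ampute_mcar(tab, "Age", rate = 0.1, seed = 7)
#' sum(amp$mask)  # 10 masked cells
#' @export
ampute_mcar <- function(table, target, rate, seed) {
  sch <- table_schema(table)
  vartype_of(sch, target)
  x <- table[[target]]
  if (anyNA(x)) {
    stop("target column '", target, "' already has missing cells", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    stop("'rate' must be a single number in [0, 1)", call. = FALSE)
  }
  n <- nrow(table)
  k <- floor(rate * n)
  rows <- if (k > 0L) with_seed(seed, sort(sample.int(n, k))) else integer(0)
  mask <- rep(FALSE, n)
  mask[rows] <- TRUE
  truth <- data.frame(row = rows,
                      original_value = vector_as_character(x[rows]),
                      stringsAsFactors = FALSE)
  out <- table
  out[[target]][mask] <- NA
  structure(list(table = out, target = target, mask = mask, truth = truth),
            class = "sice_amputed")
}

vector_as_character <- function(x) {
  if (is.numeric(x)) format_numeric_cell(x) else as.character(x)
}

#' @export
print.sice_amputed <- function(x, ...) {
  cat("<sice_amputed> target '", x$target, "': ", sum(x$mask), " of ",
      length(x$mask), " cells masked\n", sep = "")
  invisible(x)
}

#' Restore the held-out values into an amputed table
#'
#' Inverse of [ampute_mcar()]: useful for verifying that amputation only
#' touched the masked cells.
#'
#' @param amputed A `sice_amputed`.
#' @param table Table to restore into; defaults to the amputed table itself.
#' @return The original complete `sice_table`.
#' @export
restore_truth <- function(amputed, table = amputed$table) {
  sch <- table_schema(table)
  spec <- sch[[amputed$target]]
  vals <- amputed$truth$original_value
  out <- table
  restored <- if (spec$vartype == "numeric") as.numeric(vals) else vals
  out[[amputed$target]][amputed$truth$row] <- restored
  out
}

#' Typed held-out values of an amputation, in mask order
#' @param amputed A `sice_amputed`.
#' @return Numeric vector or character vector of the masked original values.
#' @export
truth_values <- function(amputed) {
  spec <- table_schema(amputed$table)[[amputed$target]]
  if (spec$vartype == "numeric") as.numeric(amputed$truth$original_value)
  else amputed$truth$original_value
}
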