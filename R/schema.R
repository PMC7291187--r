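#' Declare a column of a mixed-type table
#'
#' A variable spec names a column and fixes its measurement type. Categorical
#' types (`binary`, `nominal`, `ordinal`) carry an explicit, ordered vector of
#' admissible level labels; `ordinal` level order is meaningful and is
#' preserved through CSV round-trips. Numeric columns carry no levels.
#'
#' @param name Column name (non-empty string).
#' @param vartype One of `"binary"`, `"nominal"`, `"ordinal"`, `"numeric"`.
#' @param levels Character vector of category labels. Required for the three
#'   categorical types (`binary` must have exactly two); must be absent for
#'   `numeric`.
#' @return An object of class `sice_varspec`.
#' @examples
#' variable_spec("Gender", "binary", c("Female", "Male"))
#' variable_spec("Income", "numeric")
#' @export
variable_spec <- function(name, vartype = c("binary", "nominal", "ordinal", "numeric"),
                          levels = NULL) {
  vartype <- match.arg(vartype)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a single non-empty string", call. = FALSE)
  }
  if (vartype == "numeric") {
    if (!is.null(levels)) {
      stop("numeric column '", name, "' must not declare levels", call. = FALSE)
    }
  } else {
    if (is.null(levels) || length(levels) == 0L) {
      stop("categorical column '", name, "' requires levels", call. = FALSE)
    }
    levels <- as.character(levels)
    if (anyDuplicated(levels)) {
      stop("levels of column '", name, "' must be unique", call. = FALSE)
    }
    if (vartype == "binary" && length(levels) != 2L) {
      stop("binary column '", name, "' must have exactly 2 levels", call. = FALSE)
    }
  }
  structure(list(name = name, vartype = vartype, levels = levels),
            class = "sice_varspec")
}

#' Bundle variable specs into a table schema
#'
#' @param ... `sice_varspec` objects (or a single list of them).
#' @return An object of class `sice_schema`: a named list of variable specs.
#' @export
schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) &&
      !inherits(specs[[1]], "sice_varspec")) {
    specs <- specs[[1]]
  }
  ok <- vapply(specs, inherits, logical(1), what = "sice_varspec")
  if (length(specs) == 0L || !all(ok)) {
    stop("schema() takes one or more variable_spec objects", call. = FALSE)
  }
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate column names in schema", call. = FALSE)
  names(specs) <- nms
  structure(specs, class = "sice_schema")
}

#' @export
print.sice_schema <- function(x, ...) {
  cat("<sice_schema> ", length(x), " columns\n", sep = "")
  for (v in x) {
    lv <- if (is.null(v$levels)) "" else
      paste0(" [", paste(v$levels, collapse = " < "), "]")
    cat("  ", v$name, ": ", v$vartype, lv, "\n", sep = "")
  }
  invisible(x)
}

vartype_of <- function(sch, column) {
  if (!column %in% names(sch)) {
    stop("unknown column '", column, "'", call. = FALSE)
  }
  sch[[column]]$vartype
}

is_categorical <- function(vartype) {
  vartype %in% c("binary", "nominal", "ordinal")
}

#' Read a schema sidecar file
#'
#' The sidecar is YAML with a top-level `columns` list; each entry has `name`,
#' `vartype` and, for categorical types, ordered `levels`.
#'
#' @param path Path to the YAML file.
#' @return A `sice_schema`.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$columns)) stop("schema file has no 'columns' entry", call. = FALSE)
  specs <- lapply(y$columns, function(col) {
    variable_spec(col$name, col$vartype,
                  levels = if (!is.null(col$levels)) as.character(col$levels))
  })
  schema(specs)
}

#' Write a schema sidecar file
#'
#' @param sch A `sice_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(sch, path) {
  cols <- lapply(unclass(sch), function(v) {
    out <- list(name = v$name, vartype = v$vartype)
    if (!is.null(v$levels)) out$levels <- as.list(v$levels)
    out
  })
  names(cols) <- NULL
  yaml::write_yaml(list(columns = cols), path)
  invisible(path)
}
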