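#' Construct a mixed-type data table
#'
#' The table is a `data.frame` subclass whose columns are typed by an attached
#' schema: categorical columns are factors over exactly the schema levels
#' (`ordinal` columns are ordered factors), numeric columns are doubles.
#' Missing cells are `NA` — a dedicated sentinel, never a category level, so
#' the literal string "NA" can never be silently imputed as a value. Row order
#' is significant and preserved; rows are addressed 0-based internally and
#' reported 1-based in error messages.
#'
#' @param df A data.frame (or list of columns) with one column per schema
#'   entry, in any order; values may be character, factor, or numeric.
#' @param sch A [schema()].
#' @return An object of class `sice_table` (also a `data.frame`).
#' @export
sice_table <- function(df, sch) {
  stopifnot(inherits(sch, "sice_schema"))
  df <- as.data.frame(df, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(names(sch), names(df))
  if (length(missing_cols)) {
    stop("data lacks schema column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), names(sch))
  if (length(extra)) {
    stop("data has column(s) not in schema: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  df <- df[names(sch)]
  for (v in sch) {
    df[[v$name]] <- coerce_column(df[[v$name]], v)
  }
  structure(df, schema = sch, class = c("sice_table", "data.frame"))
}

coerce_column <- function(x, spec) {
  if (spec$vartype == "numeric") {
    if (is.factor(x)) x <- as.character(x)
    if (is.character(x)) {
      bad_txt <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
      if (any(bad_txt)) {
        stop("non-numeric value '", x[which(bad_txt)[1]], "' at (row ",
             which(bad_txt)[1], ", \"", spec$name, "\")", call. = FALSE)
      }
      x <- suppressWarnings(as.numeric(x))
    }
    x <- as.numeric(x)
    bad <- !is.na(x) & !is.finite(x)
    if (any(bad)) {
      stop("non-finite value at (row ", which(bad)[1], ", \"", spec$name,
           "\")", call. = FALSE)
    }
    x
  } else {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% spec$levels)
    if (any(bad)) {
      stop("unknown level '", x[which(bad)[1]], "' at (row ", which(bad)[1],
           ", \"", spec$name, "\")", call. = FALSE)
    }
    factor(x, levels = spec$levels, ordered = spec$vartype == "ordinal")
  }
}

#' @export
print.sice_table <- function(x, ...) {
  sch <- table_schema(x)
  cat("<sice_table> ", nrow(x), " rows x ", ncol(x), " columns (",
      sum(is.na(x)), " missing cells)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' Retrieve the schema attached to a table
#' @param table A `sice_table`.
#' @return The `sice_schema`.
#' @export
table_schema <- function(table) {
  sch <- attr(table, "schema")
  if (is.null(sch)) stop("not a sice_table: no schema attribute", call. = FALSE)
  sch
}

#' Test two tables for equality (schema, values, and missingness)
#' @param a,b `sice_table` objects.
#' @return Logical scalar.
#' @export
tables_identical <- function(a, b) {
  isTRUE(all.equal(table_schema(a), table_schema(b))) &&
    nrow(a) == nrow(b) &&
    all(vapply(names(a), function(cn) {
      xa <- a[[cn]]; xb <- b[[cn]]
      identical(is.na(xa), is.na(xb)) &&
        isTRUE(all.equal(xa[!is.na(xa)], xb[!is.na(xb)]))
    }, logical(1)))
}

#' Read a CSV file into a typed table
#'
#' Header row is mandatory and must match the schema's column names (order
#' free). Empty cells and the literal token `NA` both parse to the missing
#' marker. Every non-missing cell is validated against the schema: an unknown
#' category label or non-numeric text in a numeric column raises an error that
#' names the (1-based) row and the column.
#'
#' @param path CSV file path.
#' @param sch A [schema()] (or path to a YAML sidecar readable by
#'   [read_schema()]).
#' @return A `sice_table`.
#' @export
read_table <- function(path, sch) {
  if (is.character(sch)) sch <- read_schema(sch)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!setequal(names(df), names(sch))) {
    stop("CSV header (", paste(names(df), collapse = ", "),
         ") does not match schema columns", call. = FALSE)
  }
  sice_table(df, sch)
}

# shortest decimal representation that survives as.numeric round-trip
format_numeric_cell <- function(x) {
  out <- as.character(x)                      # 15 significant digits
  redo <- !is.na(x) & as.numeric(out) != x
  if (any(redo)) out[redo] <- sprintf("%.17g", x[redo])
  out
}

#' Write a typed table to CSV
#'
#' Missing cells are serialized as `NA`; numeric cells use the shortest
#' decimal text that parses back to the identical double, so
#' `read_table(write_table(x))` reproduces `x` exactly.
#'
#' @param table A `sice_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  sch <- table_schema(table)
  cols <- lapply(sch, function(v) {
    x <- table[[v$name]]
    out <- if (v$vartype == "numeric") format_numeric_cell(x) else as.character(x)
    out[is.na(x)] <- "NA"
    out
  })
  txt <- vapply(c(list(names(sch)), split_rows(cols, nrow(table))),
                csv_line, character(1))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

split_rows <- function(cols, n) {
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) vapply(cols, `[[`, character(1), i))
}

csv_line <- function(fields) {
  quote_me <- grepl('[",\r\n]', fields)
  fields[quote_me] <- paste0('"', gsub('"', '""', fields[quote_me]), '"')
  paste(fields, collapse = ",")
}
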