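# Design-matrix encoding used by the regression-type kernels.
# Numeric columns pass through; ordinal columns enter as integer ranks;
# binary/nominal columns as reference-level dummy indicators (first schema
# level is the reference). Factors never reach the fitters directly, so a
# column whose observed rows collapse to one level still encodes cleanly
# (all-zero dummies) instead of breaking model.matrix.
encode_predictors <- function(data, sch, exclude, intercept = TRUE) {
  cols <- setdiff(names(sch), exclude)
  pieces <- list()
  if (intercept) pieces[["(Intercept)"]] <- rep(1, nrow(data))
  for (cn in cols) {
    v <- sch[[cn]]
    x <- data[[cn]]
    if (v$vartype == "numeric") {
      pieces[[cn]] <- as.numeric(x)
    } else if (v$vartype == "ordinal") {
      pieces[[cn]] <- as.numeric(as.integer(x))
    } else {
      for (lev in v$levels[-1]) {
        pieces[[paste(cn, lev, sep = ".")]] <- as.numeric(x == lev)
      }
    }
  }
  if (length(pieces) == 0L) pieces[["(Intercept)"]] <- rep(1, nrow(data))
  mat <- do.call(cbind, pieces)
  rownames(mat) <- NULL
  mat
}

# Target encoding for PMM: numeric as-is; ordinal and binary as integer
# ranks (decoded back to levels afterwards — PMM only ever returns observed
# ranks, so decoding is exact).
encode_target_numeric <- function(y, spec) {
  switch(spec$vartype,
    numeric = as.numeric(y),
    ordinal = ,
    binary = as.numeric(as.integer(y)),
    stop("column '", spec$name, "' (", spec$vartype,
         ") cannot be encoded as a numeric target", call. = FALSE)
  )
}

decode_target_numeric <- function(vals, spec) {
  if (spec$vartype %in% c("ordinal", "binary")) {
    spec$levels[as.integer(round(vals))]
  } else {
    vals
  }
}
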