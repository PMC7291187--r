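#' Describe a single-column imputation problem
#'
#' A task pairs a target column (with rows to fill) with predictor columns
#' that are complete at call time: the unit of work every univariate kernel
#' operates on. Rows outside `mask` act as the training set.
#'
#' @param data A `sice_table` (or data.frame with a schema attribute) whose
#'   non-target columns are fully observed.
#' @param target Name of the column to impute.
#' @param mask Logical vector of rows to impute; defaults to the target's
#'   missing cells. Must select at least one row.
#' @return An object of class `sice_task`.
#' @export
impute_task <- function(data, target, mask = NULL) {
  sch <- table_schema(data)
  vartype_of(sch, target)
  if (is.null(mask)) mask <- is.na(data[[target]])
  stopifnot(is.logical(mask), length(mask) == nrow(data))
  if (!any(mask)) stop("mask selects no rows to impute", call. = FALSE)
  for (cn in setdiff(names(sch), target)) {
    if (anyNA(data[[cn]])) {
      stop("predictor column '", cn, "' has missing cells", call. = FALSE)
    }
  }
  if (all(mask | is.na(data[[target]]))) {
    stop("no observed values in target column '", target, "'", call. = FALSE)
  }
  structure(list(data = data, target = target, mask = mask, schema = sch),
            class = "sice_task")
}

task_parts <- function(task) {
  sch <- task$schema
  obs <- !task$mask & !is.na(task$data[[task$target]])
  list(sch = sch, spec = sch[[task$target]], obs = obs, mis = task$mask,
       y = task$data[[task$target]])
}

sample_one <- function(x) x[[sample.int(length(x), 1L)]]

#' Least-squares fit with a posterior coefficient draw
#'
#' The Bayesian-regression primitive shared by PMM and the BLR kernel. The
#' point estimate `b` solves the (optionally ridge-regularized) normal
#' equations; under the standard noninformative prior the residual variance
#' is drawn from its scaled inverse-chi-square posterior and a coefficient
#' vector `b_star` from `N(b, sigma2_star * (X'X + ridge I)^-1)`. A perfect
#' fit (zero residuals) collapses the posterior: `b_star == b`,
#' `sigma2_star == 0`.
#'
#' @param X Encoded predictor matrix (include an intercept column if wanted).
#' @param y Numeric response, `length(y) == nrow(X) >= 2`.
#' @param ridge Non-negative ridge penalty added to the diagonal of `X'X`.
#'   With `ridge = 0` a singular cross-product triggers an automatic fallback
#'   to `1e-6` with a warning.
#' @return An object of class `sice_blr_draw`: list with `b`, `b_star`,
#'   `sigma2_star`, and `df` (residual degrees of freedom used).
#' @examples
#' d <- draw_blr(cbind(1, 1:10), 2 * (1:10) + rnorm(10))
#' d$b
#' @export
draw_blr <- function(X, y, ridge = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || length(y) != n) {
    stop("draw_blr needs at least 2 rows and matching y length", call. = FALSE)
  }
  xtx <- crossprod(X)
  R <- try_chol(xtx + diag(ridge, p))
  if (is.null(R)) {
    warning("singular X'X: falling back to ridge = 1e-6", call. = FALSE)
    ridge <- 1e-6
    R <- chol(xtx + diag(ridge, p))
  }
  b <- drop(chol2inv(R) %*% crossprod(X, y))
  resid <- y - drop(X %*% b)
  ssr <- sum(resid^2)
  df <- max(n - p, 1L)
  if (ssr <= 1e-12 * max(1, sum(y^2))) {
    sigma2_star <- 0
    b_star <- b
  } else {
    sigma2_star <- ssr / stats::rchisq(1L, df)
    b_star <- b + sqrt(sigma2_star) * drop(backsolve(R, stats::rnorm(p)))
  }
  structure(list(b = b, b_star = b_star, sigma2_star = sigma2_star, df = df),
            class = "sice_blr_draw")
}

try_chol <- function(m) tryCatch(chol(m), error = function(e) NULL)

#' Predictive mean matching
#'
#' Fits a linear regression of the (numeric or rank-encoded ordinal) target
#' on the encoded predictors; draws posterior coefficients; predicts observed
#' rows with the point estimate `b` and missing rows with the draw `b_star`;
#' then, for each missing row, collects the `donors` observed rows whose
#' predictions are closest and copies the observed target value of one of
#' them, chosen uniformly. Imputations are therefore confined to values that
#' actually occur in the data.
#'
#' @param task An [impute_task()]; target must be numeric or ordinal.
#' @param donors Size of the donor pool (default 5, the usual convention in
#'   chained-equation engines). Must not exceed the number of observed rows.
#' @return Imputed values for the masked rows, in mask order (numeric vector,
#'   or character levels for an ordinal target).
#' @export
impute_pmm <- function(task, donors = 5L) {
  p <- task_parts(task)
  yv <- encode_target_numeric(p$y, p$spec)
  n_obs <- sum(p$obs)
  if (n_obs < donors) {
    stop("donor pool of ", donors, " exceeds ", n_obs, " observed rows",
         call. = FALSE)
  }
  X <- encode_predictors(task$data, p$sch, exclude = task$target)
  d <- draw_blr(X[p$obs, , drop = FALSE], yv[p$obs])
  eta_obs <- drop(X[p$obs, , drop = FALSE] %*% d$b)
  eta_mis <- drop(X[p$mis, , drop = FALSE] %*% d$b_star)
  y_obs <- yv[p$obs]
  out <- vapply(eta_mis, function(e) {
    pool <- order(abs(eta_obs - e))[seq_len(donors)]
    y_obs[sample_one(pool)]
  }, numeric(1))
  decode_target_numeric(out, p$spec)
}

#' Bayesian linear regression imputation
#'
#' Draws posterior coefficients and residual variance via [draw_blr()] and
#' imputes each missing row as `x' b_star + e`, `e ~ N(0, sigma2_star)` —
#' a fresh draw from the posterior predictive distribution, so repeated
#' chains produce distinct imputations.
#'
#' @param task An [impute_task()]; target must be numeric.
#' @return Numeric imputations for the masked rows.
#' @export
impute_blr <- function(task) {
  p <- task_parts(task)
  if (p$spec$vartype != "numeric") {
    stop("blr requires a numeric target", call. = FALSE)
  }
  X <- encode_predictors(task$data, p$sch, exclude = task$target)
  d <- draw_blr(X[p$obs, , drop = FALSE], as.numeric(p$y)[p$obs])
  n_mis <- sum(p$mis)
  drop(X[p$mis, , drop = FALSE] %*% d$b_star) +
    stats::rnorm(n_mis, 0, sqrt(d$sigma2_star))
}

#' Logistic regression imputation for binary targets
#'
#' Fits a binomial GLM of the target on the encoded predictors and imputes
#' each missing row by a Bernoulli draw at its fitted success probability
#' (not the argmax), so the m chains of a multiple-imputation run disagree
#' where the model is uncertain. If only one class is observed that class is
#' returned for every masked row, with a warning.
#'
#' @param task An [impute_task()]; target must be binary.
#' @return Character vector of imputed levels for the masked rows.
#' @export
impute_logreg <- function(task) {
  p <- task_parts(task)
  if (p$spec$vartype != "binary") {
    stop("logreg requires a binary target", call. = FALSE)
  }
  draw_from_class_probs(task, p, binary = TRUE)
}

#' Polytomous (multinomial) regression imputation
#'
#' Fits a multinomial logistic model on the observed rows and imputes each
#' missing row by a draw from its fitted category distribution. Single
#' observed class falls back to a constant imputation with a warning, as for
#' [impute_logreg()].
#'
#' @param task An [impute_task()]; target must be categorical.
#' @return Character vector of imputed levels for the masked rows.
#' @export
impute_polyreg <- function(task) {
  p <- task_parts(task)
  if (!is_categorical(p$spec$vartype)) {
    stop("polyreg requires a categorical target", call. = FALSE)
  }
  draw_from_class_probs(task, p, binary = FALSE)
}

draw_from_class_probs <- function(task, p, binary) {
  y_obs <- droplevels(factor(as.character(p$y[p$obs]), levels = p$spec$levels))
  n_mis <- sum(p$mis)
  if (nlevels(y_obs) < 2L) {
    warning("only one observed class in '", task$target,
            "': constant imputation", call. = FALSE)
    return(rep(levels(y_obs)[1L], n_mis))
  }
  X <- encode_predictors(task$data, p$sch, exclude = task$target,
                         intercept = binary)
  if (binary) {
    fit <- suppressWarnings(
      stats::glm.fit(X[p$obs, , drop = FALSE],
                     as.integer(y_obs == levels(y_obs)[2L]),
                     family = stats::binomial())
    )
    cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pr <- stats::plogis(drop(X[p$mis, , drop = FALSE] %*% cf))
    lv <- levels(y_obs)
    ifelse(stats::rbinom(n_mis, 1L, pr) == 1L, lv[2L], lv[1L])
  } else {
    colnames(X) <- paste0("V", seq_len(ncol(X)))
    df_obs <- as.data.frame(X[p$obs, , drop = FALSE])
    df_obs$.y <- y_obs
    fit <- nnet::multinom(.y ~ ., data = df_obs, trace = FALSE, maxit = 200L)
    pr <- stats::predict(fit, newdata = as.data.frame(X[p$mis, , drop = FALSE]),
                         type = "probs")
    lv <- levels(y_obs)
    if (is.null(dim(pr))) {
      # vector cases: P(second level) per row for 2 classes, or the
      # per-class probabilities of a single missing row
      pr <- if (length(lv) == 2L) cbind(1 - pr, pr) else matrix(pr, nrow = 1L)
    }
    apply(pr, 1L, function(w) lv[sample.int(length(lv), 1L, prob = w)])
  }
}

# Discriminant fit: class means, pooled within-class covariance (shrunk
# toward a scaled identity when singular), eigen-projection onto the
# between/within discriminant directions, Gaussian posteriors with
# proportional priors.
lda_fit <- function(X, y, shrink = 1e-4) {
  X <- as.matrix(X)
  classes <- levels(y)
  d <- ncol(X)
  counts <- table(y)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("dropping class(es) with < 2 rows from discriminant: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(y %in% small)
    X <- X[keep, , drop = FALSE]
    y <- droplevels(y[keep])
    classes <- levels(y)
    counts <- table(y)
  }
  g <- length(classes)
  n <- nrow(X)
  m <- vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
              numeric(d))
  means <- if (d == 1L) matrix(m, ncol = 1L, dimnames = list(classes, NULL))
           else t(m)
  Sw <- matrix(0, d, d)
  for (cl in classes) {
    Xc <- sweep(X[y == cl, , drop = FALSE], 2L, means[cl, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / max(n - g, 1L)
  if (is.null(try_chol(Sw))) {
    warning("singular within-class scatter: shrinkage toward identity applied",
            call. = FALSE)
    scale <- mean(diag(Sw))
    if (scale <= 0) scale <- 1
    Sw <- (1 - shrink) * Sw + shrink * scale * diag(d)
    if (is.null(try_chol(Sw))) Sw <- Sw + shrink * diag(d)
  }
  mu <- colMeans(X)
  Sb <- crossprod(sweep(means, 2L, mu) * sqrt(as.numeric(counts)))
  ev <- eigen(solve(Sw, Sb))
  ord <- order(Re(ev$values), decreasing = TRUE)
  k <- min(g - 1L, d)
  W <- Re(ev$vectors[, ord[seq_len(k)], drop = FALSE])
  Sz <- t(W) %*% Sw %*% W
  Sz <- (Sz + t(Sz)) / 2
  if (is.null(try_chol(Sz))) Sz <- Sz + shrink * diag(ncol(Sz))
  list(classes = classes, priors = as.numeric(counts) / n, means = means,
       eigvals = Re(ev$values[ord]), W = W,
       proj_means = means %*% W, proj_cov = Sz)
}

lda_posterior <- function(fit, Xnew) {
  Z <- as.matrix(Xnew) %*% fit$W
  logp <- vapply(seq_along(fit$classes), function(j) {
    log(fit$priors[j]) -
      0.5 * stats::mahalanobis(Z, fit$proj_means[j, ], fit$proj_cov)
  }, numeric(nrow(Z)))
  logp <- matrix(logp, nrow = nrow(Z))
  logp <- logp - apply(logp, 1L, max)
  pr <- exp(logp)
  pr / rowSums(pr)
}

#' Linear discriminant analysis imputation
#'
#' Computes class mean vectors and scatter matrices on the observed rows,
#' eigendecomposes the between/within-class problem, projects onto the
#' leading discriminant directions, and evaluates Gaussian class posteriors
#' for each missing row; imputed labels are drawn from those posteriors.
#' A singular within-class scatter is shrunk toward a scaled identity
#' (lambda = 1e-4) with a warning; classes with fewer than 2 observed rows
#' are dropped from the discriminant.
#'
#' @param task An [impute_task()]; target must be categorical.
#' @return Character vector of imputed levels for the masked rows.
#' @export
impute_lda <- function(task) {
  p <- task_parts(task)
  if (!is_categorical(p$spec$vartype)) {
    stop("lda requires a categorical target", call. = FALSE)
  }
  y_obs <- droplevels(factor(as.character(p$y[p$obs]), levels = p$spec$levels))
  if (nlevels(y_obs) < 2L) {
    warning("only one observed class in '", task$target,
            "': constant imputation", call. = FALSE)
    return(rep(levels(y_obs)[1L], sum(p$mis)))
  }
  X <- encode_predictors(task$data, p$sch, exclude = task$target,
                         intercept = FALSE)
  fit <- lda_fit(X[p$obs, , drop = FALSE], y_obs)
  if (length(fit$classes) < 2L) {
    warning("fewer than two usable classes: constant imputation", call. = FALSE)
    return(rep(fit$classes[1L], sum(p$mis)))
  }
  pr <- lda_posterior(fit, X[p$mis, , drop = FALSE])
  apply(pr, 1L, function(w) fit$classes[sample.int(length(w), 1L, prob = w)])
}

#' Classification and regression tree imputation
#'
#' Grows a binary tree on the observed rows (deviance splits for a numeric
#' target, Gini for categorical), routes each missing row to its leaf, and
#' imputes by a uniform draw from the observed target values in that leaf —
#' sampling rather than the leaf mean/mode, so imputation uncertainty is
#' preserved for pooling. No pruning is applied.
#'
#' @param task An [impute_task()]; any target type.
#' @param min_leaf Minimum observed rows per leaf (default 5).
#' @return Imputed values for the masked rows (numeric vector or character
#'   levels).
#' @export
impute_cart <- function(task, min_leaf = 5L) {
  p <- task_parts(task)
  numeric_target <- p$spec$vartype == "numeric"
  y_obs <- if (numeric_target) as.numeric(p$y[p$obs]) else
    droplevels(factor(as.character(p$y[p$obs]), levels = p$spec$levels))
  n_mis <- sum(p$mis)
  if (length(unique(y_obs)) == 1L) {
    v <- if (numeric_target) y_obs[1L] else as.character(y_obs[1L])
    return(rep(v, n_mis))
  }
  preds <- setdiff(names(p$sch), task$target)
  df <- as.data.frame(task$data)[preds]
  df_obs <- df[p$obs, , drop = FALSE]
  df_obs$.y <- y_obs
  fit <- rpart::rpart(
    .y ~ ., data = df_obs,
    method = if (numeric_target) "anova" else "class",
    control = rpart::rpart.control(minbucket = min_leaf,
                                   minsplit = 2L * min_leaf, cp = 1e-4,
                                   xval = 0L, maxsurrogate = 0L,
                                   usesurrogate = 0L)
  )
  node_ids <- as.numeric(rownames(fit$frame))
  leaf_obs <- node_ids[fit$where]
  fit$frame$yval <- node_ids            # predict() now returns leaf node ids
  leaf_mis <- stats::predict(fit, newdata = df[p$mis, , drop = FALSE],
                             type = "vector")
  out <- vapply(leaf_mis, function(nd) {
    pool <- which(leaf_obs == nd)
    sample_one(pool)
  }, integer(1))
  if (numeric_target) y_obs[out] else as.character(y_obs[out])
}

#' Single-imputation baselines
#'
#' Fills every masked row with a column statistic of the observed values:
#' `mean` or `median` (numeric targets), `mode` (most frequent level,
#' categorical targets; ties broken toward the earlier schema level), or
#' `random_sample` (independent uniform draws from the observed values, any
#' target type).
#'
#' @param task An [impute_task()].
#' @param kind One of `"mean"`, `"median"`, `"mode"`, `"random_sample"`.
#' @return Imputed values for the masked rows.
#' @examples
#' # the classic worked example: observed incomes 100,100,300,200,200
#' sch <- schema(variable_spec("Income", "numeric"))
#' tab <- sice_table(data.frame(Income = c(100, NA, 100, 300, NA, 200, 200)), sch)
#' impute_baseline(impute_task(tab, "Income"), "mean")  # 180 180
#' @export
impute_baseline <- function(task, kind = c("mean", "median", "mode",
                                           "random_sample")) {
  kind <- match.arg(kind)
  p <- task_parts(task)
  n_mis <- sum(p$mis)
  y_obs <- p$y[p$obs]
  if (length(y_obs) == 0L) stop("no observed values to impute from", call. = FALSE)
  numeric_target <- p$spec$vartype == "numeric"
  if (kind %in% c("mean", "median") && !numeric_target) {
    stop(kind, " imputation requires a numeric target", call. = FALSE)
  }
  if (kind == "mode" && numeric_target) {
    stop("mode imputation requires a categorical target", call. = FALSE)
  }
  val <- switch(kind,
    mean = rep(mean(as.numeric(y_obs)), n_mis),
    median = rep(stats::median(as.numeric(y_obs)), n_mis),
    mode = rep(observed_mode(y_obs, p$spec$levels), n_mis),
    random_sample = {
      pool <- if (numeric_target) as.numeric(y_obs) else as.character(y_obs)
      pool[sample.int(length(pool), n_mis, replace = TRUE)]
    })
  val
}

# most frequent level; ties resolved toward earlier schema level order
observed_mode <- function(y, levels) {
  counts <- table(factor(as.character(y), levels = levels))
  names(counts)[which.max(counts)]
}

#' Methods understood by the chained engine
#'
#' @return Character vector of method names accepted by [chain_spec()] and
#'   the `method` arguments of the CLI.
#' @export
imputation_methods <- function() {
  c("pmm", "logreg", "polyreg", "lda", "cart", "blr",
    "mean", "median", "mode", "random")
}

method_compatible <- function(method, vartype) {
  switch(method,
    pmm = vartype %in% c("numeric", "ordinal", "binary"),
    blr = ,
    mean = ,
    median = vartype == "numeric",
    logreg = vartype == "binary",
    mode = ,
    lda = ,
    polyreg = is_categorical(vartype),
    cart = ,
    random = TRUE,
    FALSE
  )
}

default_method <- function(vartype) {
  switch(vartype,
    numeric = "pmm",
    binary = "logreg",
    nominal = "polyreg",
    ordinal = "polyreg"
  )
}

# dispatch used by the engine
impute_with <- function(method, task, donors = 5L, min_leaf = 5L) {
  switch(method,
    pmm = impute_pmm(task, donors = donors),
    logreg = impute_logreg(task),
    polyreg = impute_polyreg(task),
    lda = impute_lda(task),
    cart = impute_cart(task, min_leaf = min_leaf),
    blr = impute_blr(task),
    mean = impute_baseline(task, "mean"),
    median = impute_baseline(task, "median"),
    mode = impute_baseline(task, "mode"),
    random = impute_baseline(task, "random_sample"),
    stop("unknown imputation method '", method, "'", call. = FALSE)
  )
}
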