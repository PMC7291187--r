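test_that("draw_blr recovers an exact fit with a collapsed posterior", {
  X <- matrix(1:4, ncol = 1)
  y <- c(2, 4, 6, 8)
  set.seed(1)
  d <- draw_blr(X, y)
  expect_equal(d$b, 2)
  expect_equal(d$b_star, 2)        # zero residuals: posterior collapses
  expect_identical(d$sigma2_star, 0)
})

test_that("posterior draws center on the least-squares estimate", {
  set.seed(2)
  X <- cbind(1, rnorm(40))
  y <- drop(X %*% c(1, 3)) + rnorm(40)
  b <- draw_blr(X, y)$b   # point estimate is deterministic
  draws <- replicate(10000, draw_blr(X, y)$b_star[2])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - b[2]), 3 * se + 1e-12)
})

test_that("degenerate designs fall back to ridge with a warning", {
  X <- matrix(0, nrow = 5, ncol = 1)
  y <- rnorm(5)
  set.seed(3)
  expect_warning(d <- draw_blr(X, y, ridge = 0), "ridge")
  expect_true(all(is.finite(d$b)))
  expect_error(draw_blr(matrix(1, 1, 1), 1), "at least 2 rows")
})

test_that("pmm returns the nearest donor's observed value on an exact fit", {
  # colinear observed points -> zero residuals -> b_star == b, so the
  # prediction at l = 2.05 is 20.5 and the single nearest donor holds 20
  task <- numeric_task(l = c(1, 2, 3, 2.05), k = c(10, 20, 30, NA))
  set.seed(4)
  expect_equal(impute_pmm(task, donors = 1L), 20)
})

test_that("pmm imputations are confined to observed values", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(10:30, 1)
    k <- rnorm(n, 100, 20)
    k[sample(n, 3)] <- NA
    task <- numeric_task(l = rnorm(n), k = k)
    vals <- impute_pmm(task)
    expect_true(all(vals %in% k[!is.na(k)]))
  }
})

test_that("pmm handles constant columns, donor errors, and ordinal ranks", {
  task <- numeric_task(l = 1:6, k = c(7, 7, 7, 7, 7, NA))
  set.seed(6)
  expect_equal(impute_pmm(task), 7)
  expect_error(impute_pmm(task, donors = 10L), "donor pool")

  # ordinal target imputes by rank but returns levels
  set.seed(7)
  tsk <- class_task(x = c(1, 2, 3, 4, 5, 6, 3.1),
                    g = c("low", "low", "mid", "mid", "high", "high", NA),
                    levels = c("low", "mid", "high"), vartype = "ordinal")
  vals <- replicate(20, impute_pmm(tsk, donors = 1L))
  expect_true(all(vals %in% c("low", "mid", "high")))
})

test_that("logreg draws the dominant class under perfect separation", {
  x <- c(-(10:1), 1:10) / 2
  g <- rep(c("A", "B"), each = 10)
  tsk <- class_task(x = c(x, -5), g = c(g, NA), levels = c("A", "B"),
                    vartype = "binary")
  set.seed(8)
  draws <- replicate(300, impute_logreg(tsk))
  expect_gt(mean(draws == "A"), 0.99)
})

test_that("logreg falls back to the only observed class", {
  tsk <- class_task(x = c(1, 2, 3, 4), g = c("M", "M", "M", NA),
                    levels = c("F", "M"), vartype = "binary")
  expect_warning(v <- impute_logreg(tsk), "one observed class")
  expect_identical(v, "M")
})

test_that("polyreg recovers well-separated clusters and class frequencies", {
  set.seed(9)
  x <- c(rnorm(20, -6), rnorm(20, 0), rnorm(20, 6))
  g <- rep(c("a", "b", "c"), each = 20)
  tsk <- class_task(x = c(x, 0.1), g = c(g, NA), levels = c("a", "b", "c"))
  draws <- replicate(300, impute_polyreg(tsk))
  expect_gt(mean(draws == "b"), 0.99)

  # uninformative predictor: draw frequencies reproduce observed frequencies
  set.seed(10)
  n_obs <- 400
  g2 <- sample(c("a", "b", "c"), n_obs, replace = TRUE,
               prob = c(0.7, 0.2, 0.1))
  tsk2 <- class_task(x = c(rep(0, n_obs), rep(0, 10000)),
                     g = c(g2, rep(NA, 10000)), levels = c("a", "b", "c"))
  vals <- impute_polyreg(tsk2)
  p_hat <- mean(g2 == "a")
  se <- sqrt(p_hat * (1 - p_hat) / 10000)
  expect_lt(abs(mean(vals == "a") - p_hat), 3 * se)
})

test_that("polyreg falls back on a single observed class", {
  tsk <- class_task(x = c(1, 2, 3), g = c("a", "a", NA),
                    levels = c("a", "b", "c"))
  expect_warning(v <- impute_polyreg(tsk), "one observed class")
  expect_identical(v, "a")
})

test_that("lda posteriors match the reference discriminant implementation", {
  set.seed(11)
  X <- rbind(matrix(rnorm(100, -2), 50, 2), matrix(rnorm(100, 2), 50, 2))
  y <- factor(rep(c("a", "b"), each = 50))
  fit <- sice:::lda_fit(X, y)
  post <- sice:::lda_posterior(fit, X)
  ref <- predict(MASS::lda(X, y), X)$posterior
  expect_equal(unname(post), unname(ref[, fit$classes]), tolerance = 1e-10)
  expect_equal(rowSums(post), rep(1, nrow(X)))
  expect_true(all(diff(fit$eigvals) <= 1e-9))  # sorted descending
})

test_that("lda imputes the near-certain class and respects priors", {
  set.seed(12)
  x <- c(rnorm(30, -5), rnorm(30, 5))
  g <- rep(c("c1", "c2"), each = 30)
  tsk <- class_task(x = c(x, -5), g = c(g, NA), levels = c("c1", "c2"),
                    vartype = "binary")
  draws <- replicate(300, impute_lda(tsk))
  expect_gt(mean(draws == "c1"), 0.99)

  # identical class distributions: posteriors approximate the class priors
  set.seed(13)
  x2 <- rnorm(600)
  g2 <- rep(c("c1", "c2"), each = 300)
  fit <- sice:::lda_fit(matrix(x2, ncol = 1), factor(g2))
  post <- sice:::lda_posterior(fit, matrix(rnorm(50), ncol = 1))
  expect_lt(max(abs(post[, 1] - 0.5)), 0.1)
})

test_that("lda regularizes singular scatter and drops tiny classes", {
  # constant predictor: within-class scatter singular -> shrinkage warning
  tsk <- class_task(x = c(rep(1, 8), 2), g = c(rep(c("a", "b"), 4), NA),
                    levels = c("a", "b"), vartype = "binary")
  set.seed(14)
  expect_warning(v <- impute_lda(tsk), "shrinkage")
  expect_true(v %in% c("a", "b"))

  set.seed(15)
  x <- c(rnorm(10, -3), rnorm(10, 3), 0, 0)
  g <- c(rep("a", 10), rep("b", 10), "c", NA)
  tsk2 <- class_task(x = x, g = g, levels = c("a", "b", "c"))
  expect_warning(v2 <- impute_lda(tsk2), "< 2 rows")
  expect_true(v2 %in% c("a", "b"))
})

test_that("cart routes to pure leaves and samples within leaves", {
  # x < 0 is purely "A": the missing point at -5 lands in a pure leaf
  x <- c(-(5:1), 1:5)
  g <- rep(c("A", "B"), each = 5)
  tsk <- class_task(x = c(x, -5), g = c(g, NA), levels = c("A", "B"),
                    vartype = "binary")
  set.seed(16)
  expect_true(all(replicate(50, impute_cart(tsk, min_leaf = 2L)) == "A"))

  # constant target: single leaf, constant imputation
  tsk2 <- numeric_task(l = 1:6, k = c(42, 42, 42, 42, 42, NA))
  expect_equal(impute_cart(tsk2), 42)

  # numeric target: imputations come from the observed values of the leaf
  set.seed(17)
  k <- c(rnorm(20, 0), rnorm(20, 50))
  tsk3 <- numeric_task(l = c(rep(0, 20), rep(1, 20), 1), k = c(k, NA))
  vals <- replicate(20, impute_cart(tsk3, min_leaf = 5L))
  expect_true(all(vals %in% k[21:40]))
})

test_that("cart's first split attains the exhaustive-search optimum", {
  set.seed(18)
  tested <- 0L
  for (rep in 1:40) {
    n <- sample(8:12, 1)
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    numeric_y <- rep %% 2 == 0
    y <- if (numeric_y) 2 * df$x1 + rnorm(n) else
      droplevels(factor(ifelse(df$x1 + rnorm(n, 0, 0.3) > 0, "A", "B")))
    if (!numeric_y && nlevels(y) < 2L) next
    min_leaf <- 2L
    fit <- rpart::rpart(
      y ~ ., data = cbind(df, y = y),
      method = if (numeric_y) "anova" else "class",
      control = rpart::rpart.control(minbucket = min_leaf,
                                     minsplit = 2L * min_leaf, cp = 1e-4,
                                     xval = 0L, maxsurrogate = 0L,
                                     usesurrogate = 0L))
    if (nrow(fit$frame) == 1L) next
    tested <- tested + 1L
    var <- as.character(fit$frame$var[1])
    thr <- fit$splits[1, "index"]
    left <- if (fit$splits[1, "ncat"] == -1) df[[var]] < thr else df[[var]] >= thr
    expect_gte(split_gain(y, left, numeric_y) + 1e-9,
               oracle_best_gain(df, y, min_leaf, numeric_y))
  }
  expect_gt(tested, 10L)
})

test_that("baselines reproduce the worked examples", {
  # observed incomes 100,100,300,200,200 -> mean 180 for both missing cells
  t1 <- impute_task(income_table(), "Income")
  expect_equal(impute_baseline(t1, "mean"), c(180, 180))
  expect_equal(impute_baseline(t1, "median"), c(200, 200))

  # observed death reasons have mode "Cancer" -> all three missing cells
  t3 <- impute_task(death_reason_table(), "DeathReason")
  expect_identical(impute_baseline(t3, "mode"), rep("Cancer", 3))

  # degenerate: one observed value
  t4 <- numeric_task(l = 1:3, k = c(5, NA, NA))
  expect_equal(impute_baseline(t4, "mean"), c(5, 5))
  set.seed(19)
  expect_equal(impute_baseline(t4, "random_sample"), c(5, 5))
})

test_that("baselines reject type-incompatible targets", {
  t1 <- impute_task(income_table(), "Income")
  t3 <- impute_task(death_reason_table(), "DeathReason")
  expect_error(impute_baseline(t1, "mode"), "categorical")
  expect_error(impute_baseline(t3, "mean"), "numeric")
})

test_that("every kernel is deterministic given the seed", {
  set.seed(20)
  tab <- generate_health_like(n_rows = 60, seed = 20)
  cases <- list(
    c("Age", "pmm"), c("Age", "blr"), c("Age", "cart"),
    c("Gender", "logreg"), c("Region", "polyreg"), c("Diagnosis", "lda"),
    c("Age", "mean"), c("Region", "mode"), c("Age", "random")
  )
  for (cs in cases) {
    amp <- ampute_mcar(tab, cs[1], 0.2, seed = 21)
    task <- impute_task(amp$table, cs[1])
    run <- function() {
      set.seed(99)
      sice:::impute_with(cs[2], task)
    }
    expect_identical(run(), run(), label = paste(cs, collapse = "/"))
  }
})

test_that("categorical kernels only emit schema levels", {
  set.seed(22)
  tab <- generate_health_like(n_rows = 80, seed = 22)
  for (cs in list(c("Gender", "logreg"), c("Gender", "pmm"),
                  c("Region", "polyreg"), c("Region", "lda"),
                  c("Diagnosis", "cart"), c("Region", "mode"))) {
    amp <- ampute_mcar(tab, cs[1], 0.2, seed = 23)
    vals <- sice:::impute_with(cs[2], impute_task(amp$table, cs[1]))
    lev <- table_schema(tab)[[cs[1]]]$levels
    expect_true(all(vals %in% lev), label = paste(cs, collapse = "/"))
  }
})
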