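test_that("perfect prediction scores 1 on every metric", {
  m <- confusion_metrics(c("a", "b", "a", "b"), c("a", "b", "a", "b"),
                         positive = "a")
  for (f in c("accuracy", "balanced_accuracy", "sensitivity", "precision",
              "specificity", "f_measure")) {
    expect_equal(m[[f]], 1, label = f)
  }
})

test_that("binary metrics match the hand-computed 2x2 table", {
  # TP=3 FP=1 FN=1 TN=5
  actual    <- c(rep("P", 4), rep("N", 6))
  predicted <- c("P", "P", "P", "N", "P", rep("N", 5))
  m <- confusion_metrics(actual, predicted, positive = "P")
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$f_measure, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$balanced_accuracy, (0.75 + 5 / 6) / 2)
})

test_that("binary metrics agree with the caret reference", {
  set.seed(40)
  actual <- sample(c("P", "N"), 200, replace = TRUE)
  predicted <- ifelse(runif(200) < 0.3, sample(c("P", "N"), 200, TRUE), actual)
  m <- confusion_metrics(actual, predicted, positive = "P")
  ref <- caret::confusionMatrix(factor(predicted, c("N", "P")),
                                factor(actual, c("N", "P")), positive = "P")
  expect_equal(m$accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(m$sensitivity, unname(ref$byClass["Sensitivity"]))
  expect_equal(m$specificity, unname(ref$byClass["Specificity"]))
  expect_equal(m$precision, unname(ref$byClass["Precision"]))
  expect_equal(m$f_measure, unname(ref$byClass["F1"]))
  expect_equal(m$balanced_accuracy, unname(ref$byClass["Balanced Accuracy"]))
})

test_that("degenerate predictors and zero denominators are handled", {
  m <- suppressMessages(
    confusion_metrics(c("P", "P", "N"), c("P", "P", "P"), positive = "P"))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  # all-negative predictions: precision denominator is zero -> 0 with a note
  expect_message(
    m2 <- confusion_metrics(c("P", "N"), c("N", "N"), positive = "P"),
    "zero denominator")
  expect_equal(m2$precision, 0)
  expect_equal(m2$f_measure, 0)
})

test_that("multi-class metrics are macro-averaged one-vs-rest", {
  actual    <- c("a", "a", "b", "b", "c", "c")
  predicted <- c("a", "b", "b", "b", "c", "a")
  m <- confusion_metrics(actual, predicted)
  per <- lapply(c("a", "b", "c"), function(lb) {
    tp <- sum(actual == lb & predicted == lb)
    fp <- sum(actual != lb & predicted == lb)
    fn <- sum(actual == lb & predicted != lb)
    tn <- sum(actual != lb & predicted != lb)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- tp / (tp + fn)
    c(prec = prec, sens = sens, spec = tn / (tn + fp),
      f = if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0)
  })
  avg <- rowMeans(vapply(per, identity, numeric(4)))
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$precision, unname(avg["prec"]))
  expect_equal(m$sensitivity, unname(avg["sens"]))
  expect_equal(m$specificity, unname(avg["spec"]))
  expect_equal(m$f_measure, unname(avg["f"]))
})

test_that("metric symmetries hold: pair shuffles and label swaps", {
  set.seed(41)
  actual <- sample(c("P", "N"), 100, replace = TRUE)
  predicted <- sample(c("P", "N"), 100, replace = TRUE)
  m <- confusion_metrics(actual, predicted, positive = "P")
  perm <- sample(100)
  mp <- confusion_metrics(actual[perm], predicted[perm], positive = "P")
  expect_equal(m, mp)
  msw <- confusion_metrics(actual, predicted, positive = "N")
  expect_equal(msw$sensitivity, m$specificity)
  expect_equal(msw$specificity, m$sensitivity)
})

test_that("rmse follows the direct formula and its identities", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3))$value, 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5))$value, sqrt(4 / 3))
  x <- rnorm(20)
  expect_equal(rmse(x, x + 2.5)$value, 2.5)
  expect_equal(rmse(x, x - 2.5)$value, 2.5)
  set.seed(42)
  a <- rnorm(30); b <- rnorm(30); perm <- sample(30)
  expect_equal(rmse(a, b)$value, rmse(a[perm], b[perm])$value)
})

test_that("scoring validates its inputs", {
  expect_error(rmse(1:3, 1:4), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "equal length")
  expect_error(rmse(c(1, NA), c(1, 2)), "finite")
  expect_error(confusion_metrics(c("a"), c("a", "b")), "equal length")
  expect_error(confusion_metrics(c("a", "b"), c("a", "b"), positive = "z"),
               "not among")
})

test_that("score_imputation scores only the masked cells", {
  tab <- generate_health_like(n_rows = 100, seed = 43)
  amp <- ampute_mcar(tab, "Age", 0.1, seed = 44)
  # perfect imputation: restore the truth -> RMSE 0
  perfect <- restore_truth(amp)
  expect_equal(score_imputation(perfect, amp)$value, 0)
  expect_identical(score_imputation(perfect, amp)$n, sum(amp$mask))
  # categorical target path
  ampc <- ampute_mcar(tab, "Gender", 0.1, seed = 45)
  s <- score_imputation(restore_truth(ampc), ampc)
  expect_s3_class(s, "sice_confusion")
  expect_equal(s$accuracy, 1)
})
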