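test_that("confusion counts match the double-loop oracle", {
  set.seed(3)
  true <- sample(0:4, 100, replace = TRUE)
  pred <- sample(0:4, 100, replace = TRUE)
  cm <- confusion(true, pred)
  oracle <- matrix(0L, 5, 5)
  for (i in seq_along(true)) {
    oracle[true[i] + 1, pred[i] + 1] <- oracle[true[i] + 1, pred[i] + 1] + 1L
  }
  expect_equal(unname(unclass(cm)), oracle)
  expect_equal(sum(cm), 100)
  ## row sums are the actual per-label counts
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(true, 0:4)))))
})

test_that("perfect and degenerate predictions give the expected matrices", {
  true <- rep(0:4, each = 20)
  cm <- confusion(true, true)
  expect_equal(unname(diag(cm)), rep(20L, 5))
  expect_equal(accuracy(cm), 1)
  cm0 <- confusion(true, rep(0L, 100))
  expect_equal(unname(cm0[, 1]), rep(20L, 5))
  expect_equal(sum(cm0[, -1]), 0)
  expect_error(confusion(0:3, 0:2), "length")
})

test_that("per-class metrics agree with an exhaustive counting oracle", {
  set.seed(14)
  true <- sample(0:4, 200, replace = TRUE)
  pred <- sample(0:4, 200, replace = TRUE)
  m <- class_metrics(confusion(true, pred))
  for (k in 0:4) {
    tp <- sum(true == k & pred == k)
    fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k)
    tn <- sum(true != k & pred != k)
    row <- m[m$label == k, ]
    expect_equal(row$tp, tp); expect_equal(row$fp, fp)
    expect_equal(row$fn, fn); expect_equal(row$tn, tn)
    expect_equal(row$precision, ifelse(tp + fp == 0, 0, tp / (tp + fp)))
    expect_equal(row$recall, ifelse(tp + fn == 0, 0, tp / (tp + fn)))
  }
})

test_that("F1 is the harmonic mean, reproducing the worked-example table", {
  ref <- example_metrics_table()
  expect_equal(round(f1_score(ref$precision, ref$recall), 4), ref$f1)
  ## equal precision and recall collapse to that value
  expect_equal(f1_score(0.6, 0.6), 0.6)
  expect_equal(f1_score(0, 0), 0)
})

test_that("accuracy is trace over total; the literal per-class sum is reported", {
  set.seed(5)
  true <- sample(0:4, 80, replace = TRUE)
  pred <- sample(0:4, 80, replace = TRUE)
  cm <- confusion(true, pred)
  expect_equal(accuracy(cm), sum(true == pred) / 80)
  ## per-class one-vs-rest accuracies summed without dividing by classes
  m <- class_metrics(cm)
  expect_equal(accuracy(cm, "per_class_sum"), sum((m$tp + m$tn) / 80))
  expect_error(accuracy(matrix(0, 5, 5)), "empty")
  ## zero diagonal
  cmz <- confusion(c(0, 1), c(1, 0))
  expect_equal(accuracy(cmz), 0)
})

test_that("perfectly separating scores give AUC 1 for every class", {
  true <- rep(0:4, each = 10)
  scores <- matrix(0.025, 50, 5)
  scores[cbind(seq_len(50), true + 1)] <- 0.9
  ra <- roc_auc(scores, true)
  expect_equal(unname(ra$auc), rep(1, 5))
  expect_equal(ra$average, 1)
})

test_that("the worked-example per-class AUCs average to 0.7532", {
  ref <- example_metrics_table()
  expect_equal(round(mean(ref$auc), 4), 0.7532)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(11)
  n <- 2000
  true <- sample(0:4, n, replace = TRUE)
  raw <- matrix(stats::rexp(n * 5), n, 5)
  scores <- raw / rowSums(raw)
  ra <- roc_auc(scores, true)
  ## permutation null: SE of rank AUC ~ sqrt((n1+n0+1)/(12 n1 n0))
  for (k in 0:4) {
    n1 <- sum(true == k); n0 <- n - n1
    se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
    expect_lt(abs(ra$auc[[as.character(k)]] - 0.5), 3 * se)
  }
})

test_that("rank AUC equals trapezoidal ROC integration and the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(21)
  n <- 150
  true <- sample(0:4, n, replace = TRUE)
  raw <- matrix(stats::runif(n * 5), n, 5)
  ## inject signal and ties
  raw[cbind(seq_len(n), true + 1)] <- raw[cbind(seq_len(n), true + 1)] + runif(n)
  raw <- round(raw, 1)
  scores <- raw / rowSums(raw)
  ra <- roc_auc(scores, true)
  for (k in 0:4) {
    pos <- true == k
    ## trapezoidal integration of the empirical ROC curve
    curve <- mpsuture:::roc_curve(scores[, k + 1], pos)
    trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
    expect_equal(ra$auc[[as.character(k)]], trap, tolerance = 1e-12)
    proc <- suppressMessages(as.numeric(pROC::auc(pROC::roc(pos, scores[, k + 1],
                                                            quiet = TRUE))))
    expect_equal(ra$auc[[as.character(k)]], proc, tolerance = 1e-10)
  }
})

test_that("micro-averaged recall equals trace/total accuracy", {
  set.seed(31)
  true <- sample(0:4, 120, replace = TRUE)
  pred <- sample(0:4, 120, replace = TRUE)
  cm <- confusion(true, pred)
  m <- class_metrics(cm)
  micro_recall <- sum(m$tp) / sum(m$tp + m$fn)
  expect_equal(micro_recall, accuracy(cm), tolerance = 1e-12)
})

test_that("a class absent from truth is excluded from the average with warning", {
  true <- rep(0:3, each = 5)                      # class 4 absent
  set.seed(41)
  raw <- matrix(runif(100), 20, 5)
  scores <- raw / rowSums(raw)
  expect_warning(ra <- roc_auc(scores, true), "excluded")
  expect_true(is.na(ra$auc[["4"]]))
  expect_equal(ra$average, mean(ra$auc[1:4]))
})

test_that("metrics_report assembles the full table-shaped report", {
  set.seed(51)
  true <- rep(0:4, each = 20)
  raw <- matrix(runif(500), 100, 5)
  raw[cbind(seq_len(100), true + 1)] <- raw[cbind(seq_len(100), true + 1)] + 1.2
  scores <- raw / rowSums(raw)
  rep <- metrics_report(true, scores = scores)
  expect_s3_class(rep, "mps_metrics")
  expect_equal(rep$n, 100)
  expect_equal(nrow(rep$per_class), 5)
  expect_true(all(rep$per_class$f1 >= 0 & rep$per_class$f1 <= 1))
  expect_true(all(rep$per_class$auc >= 0 & rep$per_class$auc <= 1))
  expect_equal(rep$average_auc, mean(rep$per_class$auc))
  d <- withr::local_tempdir()
  write_metrics(rep, file.path(d, "m.json"), file.path(d, "m.csv"))
  j <- jsonlite::read_json(file.path(d, "m.json"), simplifyVector = TRUE)
  expect_equal(j$accuracy, rep$accuracy, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(file.path(d, "m.csv"))), 5)
})
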