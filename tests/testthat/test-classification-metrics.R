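test_that("confusion counts partition the sample", {
  expect_equal(confusion_counts(prediction_set(c(1, 1, 0, 0), c(1, 0, 0, 0))),
               c(TP = 1, FP = 0, TN = 2, FN = 1))
  expect_equal(confusion_counts(prediction_set(rep(1, 5), rep(1, 5))),
               c(TP = 5, FP = 0, TN = 0, FN = 0))
  expect_equal(confusion_counts(prediction_set(c(1, 0), c(0, 1))),
               c(TP = 0, FP = 1, TN = 0, FN = 1))
  set.seed(1)
  yt <- rbinom(50, 1, 0.4); yp <- rbinom(50, 1, 0.5)
  expect_equal(sum(confusion_counts(prediction_set(yt, yp))), 50)
})

test_that("prediction sets validate lengths and label alphabets", {
  expect_error(prediction_set(c(1, 0), c(1, 0, 1)), "lengths differ")
  expect_error(prediction_set(c(1, 2, 3), c(1, 1, 1)), "more than two")
  expect_error(prediction_set(c(1, NA), c(1, 0)), "missing")
  expect_error(prediction_set(c(1, 0), y_score = c(0.5, NaN)), "finite")
  # arbitrary labels map through positive_label
  ps <- prediction_set(c("case", "ctrl"), c("case", "case"),
                       positive_label = "case")
  expect_equal(confusion_counts(ps), c(TP = 1, FP = 1, TN = 0, FN = 0))
})

test_that("panel values match hand-computed confusion formulas", {
  ps <- prediction_set(c(1, 1, 0, 0), c(1, 0, 0, 0))
  p <- metric_panel(ps, c("accuracy", "precision", "recall", "f1",
                          "specificity", "balanced_accuracy"))
  expect_equal(unname(p["recall"]), 0.5)
  expect_equal(unname(p["precision"]), 1.0)
  expect_equal(unname(p["f1"]), 2 / 3)
  expect_equal(unname(p["accuracy"]), 0.75)
  expect_equal(unname(p["specificity"]), 1.0)
  expect_equal(unname(p["balanced_accuracy"]), 0.75)

  perfect <- prediction_set(rep(c(1, 0), 5), rep(c(1, 0), 5),
                            y_score = rep(c(0.9, 0.1), 5))
  expect_true(all(metric_panel(perfect, supported_metrics()) == 1))
})

test_that("undefined denominators error with a hint instead of returning NaN", {
  all_neg <- prediction_set(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_error(metric_panel(all_neg, "precision"), "nothing predicted positive")
  p <- metric_panel(all_neg, c("recall", "specificity", "accuracy"))
  expect_equal(unname(p["recall"]), 0)
  expect_equal(unname(p["specificity"]), 1)
  expect_error(metric_panel(all_neg, "mcc_rescaled"), "margin")
  one_class <- prediction_set(c(1, 1), c(1, 0))
  expect_error(metric_panel(one_class, "specificity"), "no negative")
  expect_error(metric_panel(prediction_set(c(1, 0), c(1, 0)), "roc_auc"),
               "y_score")
  expect_error(metric_panel(all_neg, "not_a_metric"), "unsupported")
})

test_that("every defined panel value lies in [0, 1] and f1 is the harmonic mean", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    yt <- rbinom(n, 1, runif(1, 0.2, 0.8))
    sc <- runif(n) + yt * runif(1, 0, 1)
    yp <- as.integer(sc > stats::median(sc))
    ps <- prediction_set(yt, yp, sc)
    p <- tryCatch(metric_panel(ps, supported_metrics()), error = function(e) NULL)
    if (is.null(p)) next # a legitimately undefined metric for this draw
    expect_true(all(p >= 0 & p <= 1))
    pr <- p[["precision"]]; rc <- p[["recall"]]
    if (pr + rc > 0) {
      expect_equal(p[["f1"]], 2 * pr * rc / (pr + rc), tolerance = 1e-12)
    }
  }
})

test_that("swapping the positive label exchanges recall and specificity", {
  set.seed(37)
  for (i in 1:20) {
    n <- 40
    yt <- rbinom(n, 1, 0.5); yp <- rbinom(n, 1, 0.5)
    if (length(unique(yt)) < 2 || length(unique(yp)) < 2) next
    a <- metric_panel(prediction_set(yt, yp, positive_label = 1),
                      c("recall", "specificity"))
    b <- metric_panel(prediction_set(yt, yp, positive_label = 0),
                      c("recall", "specificity"))
    expect_equal(unname(a["recall"]), unname(b["specificity"]))
    expect_equal(unname(a["specificity"]), unname(b["recall"]))
    # precision under the swapped label is the negative predictive value
    cc <- confusion_counts(prediction_set(yt, yp))
    if (cc[["TN"]] + cc[["FN"]] > 0) {
      b_prec <- metric_panel(prediction_set(yt, yp, positive_label = 0),
                             "precision")
      expect_equal(unname(b_prec), cc[["TN"]] / (cc[["TN"]] + cc[["FN"]]))
    }
  }
})

test_that("roc_auc matches the pairwise oracle and honours tie conventions", {
  yt <- c(1, 0, 1, 1, 0, 0, 1, 0)
  expect_equal(unname(metric_panel(prediction_set(yt, y_score = yt), "roc_auc")), 1)
  expect_equal(unname(metric_panel(prediction_set(yt, y_score = -yt), "roc_auc")), 0)
  expect_equal(unname(metric_panel(prediction_set(yt, y_score = rep(0.3, 8)),
                                   "roc_auc")), 0.5)
  set.seed(41)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 1) # coarse grid forces ties
    expect_equal(unname(metric_panel(prediction_set(y, y_score = s), "roc_auc")),
                 brute_auc(y, s), tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- runif(30)
    ours <- unname(metric_panel(prediction_set(y, y_score = s), "roc_auc"))
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("step-wise average precision reproduces reference values", {
  ap <- function(y, s) {
    unname(metric_panel(prediction_set(y, y_score = s), "average_precision"))
  }
  # expected values frozen from an independent reference implementation
  expect_equal(ap(c(1, 0, 1), c(0.9, 0.8, 0.7)), 0.833333333333,
               tolerance = 1e-9)
  expect_equal(ap(c(1, 1, 0, 0), c(0.9, 0.6, 0.7, 0.2)), 0.833333333333,
               tolerance = 1e-9)
  expect_equal(ap(c(0, 1, 1, 0, 1), c(0.5, 0.5, 0.8, 0.1, 0.3)),
               0.805555555556, tolerance = 1e-9)
  expect_equal(ap(c(1, 0, 0, 1, 1, 0, 1, 0),
                  c(0.8, 0.8, 0.3, 0.6, 0.9, 0.5, 0.2, 0.1)),
               0.747023809524, tolerance = 1e-9)
  # AP of a perfect ranking is 1; of no positives, an error
  expect_equal(ap(c(0, 1, 0, 1), c(0.1, 0.8, 0.2, 0.9)), 1)
  expect_error(ap(c(0, 0), c(0.2, 0.4)), "no positive")
})

test_that("mcc_rescaled lives on [0, 1] with 0.5 at chance", {
  ps <- prediction_set(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unname(metric_panel(ps, "mcc_rescaled")), 1)
  anti <- prediction_set(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(unname(metric_panel(anti, "mcc_rescaled")), 0)
  # independent predictions give MCC 0 -> rescaled 0.5
  ind <- prediction_set(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unname(metric_panel(ind, "mcc_rescaled")), 0.5)
})
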