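#' Bundle binary-classification predictions
#'
#' Holds true labels, hard predicted labels, and optionally continuous
#' scores for one model on one dataset. Labels are mapped to 0/1 using
#' `positive_label`; scores are required only for ranking metrics
#' (`roc_auc`, `average_precision`).
#'
#' @param y_true true class labels.
#' @param y_pred predicted class labels, same length; may be `NULL` if only
#'   ranking metrics will be requested.
#' @param y_score optional continuous scores, same length; larger = more
#'   positive.
#' @param positive_label the label value counted as the positive class
#'   (default `1`).
#' @return an object of class `prediction_set` with `y_true`/`y_pred` coded
#'   0/1 and `y_score` as given.
#' @export
prediction_set <- function(y_true, y_pred = NULL, y_score = NULL,
                           positive_label = 1) {
  n <- length(y_true)
  if (n < 1L) stop("empty prediction set", call. = FALSE)
  if (!is.null(y_pred) && length(y_pred) != n) {
    stop("y_true and y_pred lengths differ (", n, " vs ", length(y_pred), ")",
         call. = FALSE)
  }
  if (!is.null(y_score)) {
    if (length(y_score) != n) {
      stop("y_true and y_score lengths differ", call. = FALSE)
    }
    if (!is.numeric(y_score) || any(!is.finite(y_score))) {
      stop("y_score must be finite numeric", call. = FALSE)
    }
  }
  code <- function(y, what) {
    out <- as.integer(y == positive_label)
    lv <- unique(y)
    if (length(lv) > 2L) {
      stop(what, " has more than two distinct labels: ",
           paste(utils::head(lv, 5), collapse = ", "), call. = FALSE)
    }
    if (any(is.na(y))) stop(what, " contains missing labels", call. = FALSE)
    out
  }
  structure(
    list(
      y_true = code(y_true, "y_true"),
      y_pred = if (!is.null(y_pred)) code(y_pred, "y_pred"),
      y_score = y_score,
      positive_label = positive_label
    ),
    class = "prediction_set"
  )
}

#' Confusion-matrix counts
#'
#' @param preds a `prediction_set` with `y_pred` present.
#' @return named integer vector `c(TP, FP, TN, FN)`; the four counts sum to
#'   the sample size.
#' @export
#' @examples
#' confusion_counts(prediction_set(c(1, 1, 0, 0), c(1, 0, 0, 0)))
confusion_counts <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  if (is.null(preds$y_pred)) {
    stop("prediction set has no predicted labels", call. = FALSE)
  }
  yt <- preds$y_true
  yp <- preds$y_pred
  c(
    TP = sum(yt == 1L & yp == 1L),
    FP = sum(yt == 0L & yp == 1L),
    TN = sum(yt == 0L & yp == 0L),
    FN = sum(yt == 1L & yp == 0L)
  )
}

#' Supported metric names
#' @return character vector of metric names [metric_panel()] understands.
#' @export
supported_metrics <- function() {
  c("accuracy", "balanced_accuracy", "precision", "recall", "specificity",
    "f1", "mcc_rescaled", "average_precision", "roc_auc")
}

#' Default metric panel
#' @return the metric names computed when [metric_panel()] is called
#'   without an explicit selection.
#' @export
default_panel_metrics <- function() {
  c("accuracy", "balanced_accuracy", "precision", "recall", "f1",
    "average_precision", "roc_auc")
}

# ROC AUC by the rank statistic (equivalent to the trapezoidal rule over
# unique thresholds; ties contribute 1/2, the midpoint convention).
roc_auc_score <- function(y_true, y_score) {
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc undefined: need at least one positive and one negative ",
         "instance", call. = FALSE)
  }
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Step-wise average precision: AP = sum_k (R_k - R_{k-1}) * P_k over
# decreasing unique score thresholds (no interpolation). Tied scores enter
# at the same threshold.
average_precision_score <- function(y_true, y_score) {
  n_pos <- sum(y_true == 1L)
  if (n_pos == 0L) {
    stop("average_precision undefined: no positive instances", call. = FALSE)
  }
  o <- order(y_score, decreasing = TRUE)
  yt <- y_true[o]
  sc <- y_score[o]
  tp <- cumsum(yt == 1L)
  pp <- seq_along(yt)
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE) # last index of each threshold
  tp <- tp[keep]
  pp <- pp[keep]
  recall <- tp / n_pos
  precision <- tp / pp
  sum(diff(c(0, recall)) * precision)
}

#' Standard binary-classification metric panel
#'
#' Computes the requested metrics from a prediction set using the standard
#' confusion-matrix and ranking definitions, returning a named vector whose
#' values all live on \[0, 1\] so they can feed directly into
#' [compute_mlcps()]. The Matthews correlation coefficient is offered only in
#' rescaled form, `(MCC + 1) / 2`, to respect the common-scale requirement.
#'
#' Undefined metrics (e.g. precision when nothing was predicted positive)
#' raise an error rather than silently returning 0 or `NaN`: a fabricated
#' zero ray would annihilate two triangle terms of the polygon area and
#' distort comparisons.
#'
#' @param preds a [prediction_set()].
#' @param metrics character vector of metric names from
#'   [supported_metrics()]; the default panel is accuracy, balanced
#'   accuracy, precision, recall, f1, average precision and ROC AUC.
#' @return named numeric vector of metric scores, in the requested order.
#' @export
#' @examples
#' ps <- prediction_set(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' metric_panel(ps, c("accuracy", "precision", "recall", "f1"))
metric_panel <- function(preds, metrics = default_panel_metrics()) {
  stopifnot(inherits(preds, "prediction_set"))
  unknown <- setdiff(metrics, supported_metrics())
  if (length(unknown)) {
    stop("unsupported metrics: ", paste(unknown, collapse = ", "),
         "; supported: ", paste(supported_metrics(), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metrics)) stop("duplicated metric names", call. = FALSE)
  score_based <- intersect(metrics, c("average_precision", "roc_auc"))
  if (length(score_based) && is.null(preds$y_score)) {
    stop("metrics ", paste(score_based, collapse = ", "),
         " need continuous scores; supply y_score", call. = FALSE)
  }
  label_based <- setdiff(metrics, c("average_precision", "roc_auc"))
  cc <- NULL
  if (length(label_based)) cc <- confusion_counts(preds)

  need <- function(denom, metric, ...) {
    if (denom == 0) {
      stop(metric, " undefined: ", ..., call. = FALSE)
    }
  }
  one <- function(metric) {
    TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
    switch(metric,
      accuracy = (TP + TN) / (TP + FP + TN + FN),
      balanced_accuracy = {
        need(TP + FN, metric, "no positive instances in y_true")
        need(TN + FP, metric, "no negative instances in y_true")
        (TP / (TP + FN) + TN / (TN + FP)) / 2
      },
      precision = {
        need(TP + FP, metric,
             "nothing predicted positive (TP + FP = 0); inspect the ",
             "decision threshold or drop precision from the panel")
        TP / (TP + FP)
      },
      recall = {
        need(TP + FN, metric, "no positive instances in y_true")
        TP / (TP + FN)
      },
      specificity = {
        need(TN + FP, metric, "no negative instances in y_true")
        TN / (TN + FP)
      },
      f1 = {
        need(2 * TP + FP + FN, metric,
             "no positives in truth or prediction")
        2 * TP / (2 * TP + FP + FN)
      },
      mcc_rescaled = {
        denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
        need(denom, metric, "a confusion-matrix margin is zero")
        mcc <- (TP * TN - FP * FN) / sqrt(denom)
        (mcc + 1) / 2
      },
      average_precision = average_precision_score(preds$y_true, preds$y_score),
      roc_auc = roc_auc_score(preds$y_true, preds$y_score)
    )
  }
  vapply(metrics, one, numeric(1))
}
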