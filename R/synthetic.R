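#' Simulate a binary classifier of controlled quality
#'
#' Generates labels and scores from a two-class Gaussian score model:
#' labels are Bernoulli(`class_balance`); each instance receives a latent
#' score `z ~ N(+separation/2, 1)` for positives and `N(-separation/2, 1)`
#' for negatives. The reported score is the calibrated posterior
#' probability of the positive class,
#' `plogis(qlogis(class_balance) + separation * z)` (the log-likelihood
#' ratio of two unit-variance Gaussians is linear in `z`), and hard labels
#' are obtained by thresholding that probability.
#'
#' Consequences used throughout the test-suite: the expected ROC AUC is
#' `pnorm(separation / sqrt(2))`, so `separation = 0` yields a chance-level
#' classifier (constant scores, AUC 0.5 under the tie convention) whose
#' accuracy approaches `max(class_balance, 1 - class_balance)` because the
#' constant posterior equals the class prior, i.e. it predicts the majority
#' class.
#'
#' @param n_samples number of instances.
#' @param class_balance fraction of positives, in (0, 1).
#' @param separation difference between the class-conditional score means
#'   (>= 0); 0 = uninformative, ~3 = excellent.
#' @param threshold decision threshold on the probability scale
#'   (default 0.5); predictions are `probability >= threshold`.
#' @param seed integer seed; identical seeds give identical output, and the
#'   global RNG state is left untouched.
#' @return a [prediction_set()] with `y_true`, `y_pred`, `y_score`.
#' @export
#' @examples
#' ps <- simulate_classifier(200, separation = 2, seed = 7)
#' metric_panel(ps)
simulate_classifier <- function(n_samples, class_balance = 0.5,
                                separation = 1, threshold = 0.5,
                                seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != trunc(n_samples)) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(class_balance) || class_balance <= 0 || class_balance >= 1) {
    stop("`class_balance` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(separation) || separation < 0) {
    stop("`separation` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  sim <- withr::with_seed(as.integer(seed), {
    y <- stats::rbinom(n_samples, 1L, class_balance)
    z <- stats::rnorm(n_samples,
                      mean = ifelse(y == 1L, separation / 2, -separation / 2))
    list(y = y, z = z)
  })
  prob <- stats::plogis(stats::qlogis(class_balance) + separation * sim$z)
  prediction_set(
    y_true = sim$y,
    y_pred = as.integer(prob >= threshold),
    y_score = prob
  )
}

#' Generate a synthetic metrics table
#'
#' Three structures with known ground truth:
#' * `"random"` — i.i.d. Uniform(0, 1) cells; no ordering implied.
#' * `"dominated"` — model `k` strictly exceeds model `k + 1` in *every*
#'   metric (each model's values are drawn from its own disjoint band of
#'   \[0, 1\]), so the true ranking is the generation order and, because the
#'   polygon area is monotone in each ray, any scoring geometry must
#'   recover it.
#' * `"constant"` — all models identical; every scorer must tie them.
#'
#' @param n_models number of rows (>= 1).
#' @param n_metrics number of columns (>= 3).
#' @param structure one of `"random"`, `"dominated"`, `"constant"`.
#' @param seed integer seed; global RNG state is untouched.
#' @return a [metrics_table()] with models `model_01`, `model_02`, ... (in
#'   `"dominated"` tables, `model_01` is the strictly best one) and metrics
#'   `metric_1`, ...
#' @export
make_metric_table <- function(n_models, n_metrics,
                              structure = c("random", "dominated", "constant"),
                              seed = 1L) {
  structure_kind <- match.arg(structure)
  if (n_models < 1L) stop("`n_models` must be >= 1", call. = FALSE)
  if (n_metrics < 3L) stop("`n_metrics` must be >= 3", call. = FALSE)
  values <- withr::with_seed(as.integer(seed), {
    switch(structure_kind,
      random = matrix(stats::runif(n_models * n_metrics),
                      nrow = n_models, ncol = n_metrics),
      dominated = {
        # model k draws from ((K - k) / K, (K - k + 1) / K): disjoint bands
        # guarantee strict coordinate-wise dominance of earlier models.
        K <- n_models
        t(vapply(seq_len(K), function(k) {
          lo <- (K - k) / K
          stats::runif(n_metrics, min = lo + 0.05 / K, max = lo + 0.95 / K)
        }, numeric(n_metrics)))
      },
      constant = {
        row <- stats::runif(n_metrics, min = 0.3, max = 0.9)
        matrix(rep(row, each = n_models), nrow = n_models)
      }
    )
  })
  dimnames(values) <- list(
    sprintf("model_%02d", seq_len(n_models)),
    paste0("metric_", seq_len(n_metrics))
  )
  metrics_table(values)
}
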