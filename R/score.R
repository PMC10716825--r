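#' Included angle between adjacent metric rays
#'
#' When `n_metrics` metrics are projected onto a polar plane as equally
#' spaced rays, the full circle is split evenly: the included angle between
#' two adjacent rays is `2 * pi / n_metrics` radians (360 degrees divided by
#' the number of metrics).
#'
#' @param n_metrics a single positive integer, the number of metrics/rays.
#' @return the included angle in radians.
#' @export
#' @examples
#' compute_angle(4) # pi / 2
compute_angle <- function(n_metrics) {
  if (!is.numeric(n_metrics) || length(n_metrics) != 1L ||
      !is.finite(n_metrics) || n_metrics < 1 ||
      n_metrics != trunc(n_metrics)) {
    stop("`n_metrics` must be a single positive integer", call. = FALSE)
  }
  2 * pi / n_metrics
}

#' Apply per-metric weights to a metric vector
#'
#' Each metric score is multiplied by its weight. Metrics not mentioned in
#' `weights` keep weight 1, so an empty weight vector is the identity. A
#' weight of exactly zero excludes the metric: it is removed from the vector,
#' and downstream scoring recomputes the ray count and included angle on the
#' reduced set.
#'
#' @param metrics named numeric vector of metric scores.
#' @param weights named numeric vector of non-negative weights, or `NULL`.
#'   Names must refer to metrics present in `metrics`.
#' @return a named numeric vector: weighted scores, zero-weight metrics
#'   dropped, original order otherwise preserved.
#' @export
#' @examples
#' apply_weights(c(accuracy = 0.8, f1 = 0.6), c(f1 = 2))
#' apply_weights(c(accuracy = 0.8, f1 = 0.6, recall = 0.7), c(recall = 0))
apply_weights <- function(metrics, weights = NULL) {
  validate_metric_vector(metrics)
  weights <- validate_weight_vector(weights)
  if (is.null(weights) || length(weights) == 0L) return(metrics)
  unknown <- setdiff(names(weights), names(metrics))
  if (length(unknown)) {
    stop("weights refer to metrics absent from the input: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  w <- stats::setNames(rep(1, length(metrics)), names(metrics))
  w[names(weights)] <- weights
  out <- metrics * w
  out[w > 0]
}

max_polygon_area <- function(n, upper_bound) {
  (n / 2) * sin(2 * pi / n) * upper_bound^2
}

#' Cumulative performance score of one model
#'
#' Projects the (optionally weighted) metric values as rays on a polar plane,
#' equally spaced in the vector's stated order, and returns the area of the
#' closed polygon whose vertices are the ray tips. The plane decomposes into
#' `n` triangles, one per adjacent ray pair; each has area
#' `(1/2) * d_i * d_{i+1} * sin(theta)` with `theta = 2*pi/n`, so the total is
#'
#' \deqn{Area = \frac{1}{2} \sin\theta \sum_{i=1}^{n} d_i d_{i+1},
#'       \quad d_{n+1} = d_1.}
#'
#' The cyclic convention `d_{n+1} = d_1` closes the polygon. The score is
#' invariant to cyclic rotation and to reversal of the metric ordering but
#' not to arbitrary permutations, so comparisons across models are only
#' meaningful with a shared ordering (see [compute_mlcps_table()]).
#'
#' @param metrics named numeric vector of metric scores (non-negative,
#'   finite; at least 3 must survive weighting).
#' @param weights optional named non-negative weights; zero weight excludes
#'   a metric (see [apply_weights()]).
#' @param upper_bound declared common upper bound of the metric scale
#'   (default 1). Values above it trigger a warning, not an error, since
#'   weights above 1 legitimately push scores past the bound.
#' @param model_name label carried into the result.
#' @return an object of class `mlcps_result`: a list with `model_name`,
#'   `score` (the polygon area), `normalized_score` (area divided by the
#'   maximum area attainable with the same geometry and all rays at
#'   `upper_bound`, clamped to \[0, 1\]; a convenience, not part of the
#'   original formulation), `geometry` (`n_metrics`, `angle_rad`,
#'   `ordering`), `effective_metrics`, `weighted`.
#' @export
#' @examples
#' compute_mlcps(c(accuracy = 1, precision = 1, recall = 1, f1 = 1))$score # 2
#' compute_mlcps(c(a = 0.8, b = 0.6, c = 0.9, d = 0.7), weights = c(d = 0))
compute_mlcps <- function(metrics, weights = NULL, upper_bound = 1,
                          model_name = "model") {
  if (!is.numeric(upper_bound) || length(upper_bound) != 1L ||
      !is.finite(upper_bound) || upper_bound <= 0) {
    stop("`upper_bound` must be a single positive number", call. = FALSE)
  }
  d <- apply_weights(metrics, weights)
  n <- length(d)
  if (n < 3L) {
    stop("degenerate geometry: need at least 3 metrics after zero-weight ",
         "exclusion to form a polygon, got ", n, call. = FALSE)
  }
  over <- d > upper_bound
  if (any(over)) {
    warning("metric values exceed the declared upper bound (", upper_bound,
            "): ", paste(names(d)[over], collapse = ", "), call. = FALSE)
  }
  theta <- compute_angle(n)
  area <- 0.5 * sin(theta) * sum(d * c(d[-1L], d[[1L]]))
  norm <- area / max_polygon_area(n, upper_bound)
  if (norm > 1) {
    message("normalized score ", format(norm), " clamped to 1 ",
            "(values exceed the declared upper bound)")
    norm <- 1
  }
  structure(
    list(
      model_name = model_name,
      score = area,
      normalized_score = norm,
      geometry = list(n_metrics = n, angle_rad = theta, ordering = names(d)),
      effective_metrics = names(d),
      weighted = !is.null(weights) && length(weights) > 0L
    ),
    class = "mlcps_result"
  )
}

#' @export
print.mlcps_result <- function(x, ...) {
  cat(sprintf("<mlcps_result> %s\n", x$model_name))
  cat(sprintf("  score: %.6f  (normalized: %.6f)\n",
              x$score, x$normalized_score))
  cat(sprintf("  geometry: n = %d rays, angle = %.4f rad%s\n",
              x$geometry$n_metrics, x$geometry$angle_rad,
              if (x$weighted) ", weighted" else ""))
  cat("  metrics:", paste(x$effective_metrics, collapse = ", "), "\n")
  invisible(x)
}

#' Score every model of a metrics table
#'
#' Applies [compute_mlcps()] row-wise with one shared geometry: the ray
#' ordering is the table's column order, identical for every model, which is
#' what makes the resulting scores comparable.
#'
#' @param table a `metrics_table` (see [metrics_table()]), or a numeric
#'   matrix/data frame with model row names and metric column names.
#' @param weights optional named non-negative weights (see
#'   [apply_weights()]).
#' @param upper_bound declared metric upper bound; defaults to the table's
#'   own `upper_bound` (1 for plain matrices).
#' @return a tibble with one row per model: `model`, `mlcps`,
#'   `mlcps_normalized`, `effective_metrics` (comma-separated), `weighted`;
#'   the shared geometry is attached as attribute `"geometry"`.
#' @export
compute_mlcps_table <- function(table, weights = NULL, upper_bound = NULL) {
  table <- as_metrics_table(table)
  if (is.null(upper_bound)) upper_bound <- table$upper_bound
  m <- table$values
  if (nrow(m) == 0L) stop("metrics table has no models", call. = FALSE)
  results <- lapply(rownames(m), function(model) {
    r <- tryCatch(
      compute_mlcps(m[model, ], weights = weights,
                    upper_bound = upper_bound, model_name = model),
      error = function(e) {
        stop("model '", model, "': ", conditionMessage(e), call. = FALSE)
      }
    )
    r
  })
  geom <- results[[1L]]$geometry
  out <- tibble::tibble(
    model = vapply(results, `[[`, character(1), "model_name"),
    mlcps = vapply(results, `[[`, numeric(1), "score"),
    mlcps_normalized = vapply(results, `[[`, numeric(1), "normalized_score"),
    effective_metrics = vapply(
      results, function(r) paste(r$effective_metrics, collapse = ","),
      character(1)
    ),
    weighted = vapply(results, `[[`, logical(1), "weighted")
  )
  attr(out, "geometry") <- geom
  out
}
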