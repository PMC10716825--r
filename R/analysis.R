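#' Standard deviation of one model's metric scores
#'
#' The dispersion of a model's raw metric panel, used as a classical
#' consistency baseline: a model whose metrics all sit at a similar level
#' has a small SD. The comparison against the cumulative performance score
#' (see [compare_rankings()]) exists precisely because a uniformly *poor*
#' model also has a small SD — dispersion alone ignores magnitude.
#'
#' @param metrics named numeric vector with at least two values.
#' @return the sample standard deviation (n - 1 denominator).
#' @export
#' @examples
#' metric_sd(c(a = 0, b = 1)) # sqrt(0.5)
metric_sd <- function(metrics) {
  validate_metric_vector(metrics)
  if (length(metrics) < 2L) {
    stop("metric SD needs at least 2 values", call. = FALSE)
  }
  stats::sd(metrics)
}

rank_desc_min <- function(x) {
  # rank 1 = largest; ties share the minimum (best) rank
  rank(-x, ties.method = "min")
}

#' Rank models by cumulative performance score, with an SD baseline
#'
#' Scores every model of `table_a`, ranks them by score (rank 1 = highest)
#' and by the standard deviation of their raw metric panel (rank 1 =
#' smallest SD), and — when a second table is supplied, typically the same
#' models evaluated on an independent test set — reports rank agreement
#' between the two score orderings.
#'
#' The SD column always uses the raw, unweighted metrics even when `weights`
#' is supplied: it is a descriptive baseline of the panel as measured, not
#' of the reweighted geometry.
#'
#' @param table_a a [metrics_table()] (or matrix/data frame coercible to
#'   one).
#' @param table_b optional second table with the same model and metric
#'   names (order may differ; rows are matched by model name, columns are
#'   taken in `table_a`'s order so both tables share one geometry).
#' @param weights optional named non-negative weights applied to the score
#'   (not to the SD).
#' @param upper_bound declared metric upper bound; default taken from
#'   `table_a`.
#' @return a `ranking_report`: a tibble with columns `model`, `mlcps`,
#'   `mlcps_normalized`, `sd`, `rank_mlcps`, `rank_sd`, `tie_mlcps`,
#'   `effective_metrics`, and when `table_b` is given also `mlcps_b`,
#'   `rank_mlcps_b`, `rank_agree`. Rows are ordered by `rank_mlcps`, ties
#'   broken by model name. With `table_b`, attributes `n_rank_identical`
#'   (models keeping the same score rank in both tables) and
#'   `spearman_rho` (Spearman correlation of the two score vectors) are
#'   attached.
#' @export
compare_rankings <- function(table_a, table_b = NULL, weights = NULL,
                             upper_bound = NULL) {
  table_a <- as_metrics_table(table_a)
  scores_a <- compute_mlcps_table(table_a, weights = weights,
                                  upper_bound = upper_bound)
  sds <- apply(table_a$values, 1L, stats::sd)
  out <- scores_a
  out$sd <- unname(sds[out$model])
  out$rank_mlcps <- rank_desc_min(out$mlcps)
  out$rank_sd <- rank(out$sd, ties.method = "min")
  out$tie_mlcps <- duplicated(out$mlcps) | duplicated(out$mlcps, fromLast = TRUE)

  if (!is.null(table_b)) {
    table_b <- as_metrics_table(table_b)
    if (!setequal(rownames(table_b$values), out$model)) {
      stop("table_b model names do not match table_a", call. = FALSE)
    }
    if (!setequal(colnames(table_b$values), colnames(table_a$values))) {
      stop("table_b metric names do not match table_a", call. = FALSE)
    }
    vb <- table_b$values[out$model, colnames(table_a$values), drop = FALSE]
    scores_b <- compute_mlcps_table(
      metrics_table(vb, upper_bound = table_b$upper_bound),
      weights = weights, upper_bound = upper_bound
    )
    out$mlcps_b <- scores_b$mlcps[match(out$model, scores_b$model)]
    out$rank_mlcps_b <- rank_desc_min(out$mlcps_b)
    out$rank_agree <- out$rank_mlcps == out$rank_mlcps_b
  }

  ord <- order(out$rank_mlcps, out$model)
  out <- out[ord, ]
  out <- out[, c("model", "mlcps", "mlcps_normalized", "sd",
                 "rank_mlcps", "rank_sd", "tie_mlcps", "effective_metrics",
                 intersect(c("mlcps_b", "rank_mlcps_b", "rank_agree"),
                           names(out)))]
  if (!is.null(table_b)) {
    attr(out, "n_rank_identical") <- sum(out$rank_agree)
    attr(out, "spearman_rho") <-
      stats::cor(out$mlcps, out$mlcps_b, method = "spearman")
  }
  attr(out, "geometry") <- attr(scores_a, "geometry")
  class(out) <- c("ranking_report", class(out))
  out
}

#' @export
print.ranking_report <- function(x, ...) {
  geom <- attr(x, "geometry")
  cat(sprintf("Cumulative performance score ranking (%d models, %d rays, angle %.4f rad)\n",
              nrow(x), geom$n_metrics, geom$angle_rad))
  cat("Ray order:", paste(geom$ordering, collapse = " > "), "\n\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "spearman_rho"))) {
    cat(sprintf("\nCross-table agreement: %d/%d identical score ranks, Spearman rho = %.4f\n",
                attr(x, "n_rank_identical"), nrow(x), attr(x, "spearman_rho")))
  }
  invisible(x)
}
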