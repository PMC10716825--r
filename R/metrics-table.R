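#' Construct a metrics table
#'
#' The central input container: a rectangular matrix of precomputed metric
#' scores with models as rows and metrics as columns. Column order matters —
#' it is the order in which rays are laid out on the polar plane — so it is
#' preserved exactly as supplied (or as read from file).
#'
#' @param values numeric matrix or data frame; rows = models, columns =
#'   metrics. A data frame may carry model names either as row names or in a
#'   first non-numeric column.
#' @param upper_bound declared common upper bound of the metric scale
#'   (default 1); values above it are allowed but trigger warnings at
#'   scoring time.
#' @return an object of class `metrics_table`: a list with `values` (numeric
#'   matrix with model row names and metric column names) and `upper_bound`.
#' @export
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("m", 1:3),
#'                             c("accuracy", "precision", "recall", "f1")))
#' metrics_table(m)
metrics_table <- function(values, upper_bound = 1) {
  if (is.data.frame(values)) {
    first_col_names <- ncol(values) >= 2L && !is.numeric(values[[1L]])
    if (first_col_names) {
      rn <- as.character(values[[1L]])
      values <- values[, -1L, drop = FALSE]
      rownames(values) <- rn
    }
    values <- as.matrix(values)
  }
  if (!is.matrix(values)) stop("`values` must be a matrix or data frame",
                               call. = FALSE)
  if (!is.numeric(values)) {
    stop("metrics table contains non-numeric cells", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("model_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values)) || any(!nzchar(colnames(values)))) {
    stop("every metric column must be named", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate model names: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate metric names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (ncol(values) < 3L) {
    stop("need at least 3 metric columns to form a polygon, got ",
         ncol(values), call. = FALSE)
  }
  na_cells <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(na_cells)) {
    stop("missing or non-finite cell at model '",
         rownames(values)[na_cells[1, 1]], "', metric '",
         colnames(values)[na_cells[1, 2]], "'", call. = FALSE)
  }
  if (!is.numeric(upper_bound) || length(upper_bound) != 1L ||
      !is.finite(upper_bound) || upper_bound <= 0) {
    stop("`upper_bound` must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, upper_bound = upper_bound),
            class = "metrics_table")
}

#' Coerce to a metrics table
#' @param x a `metrics_table`, matrix, or data frame.
#' @param ... passed to [metrics_table()].
#' @export
as_metrics_table <- function(x, ...) {
  if (inherits(x, "metrics_table")) x else metrics_table(x, ...)
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("<metrics_table> %d models x %d metrics (upper bound %g)\n",
              nrow(x$values), ncol(x$values), x$upper_bound))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
dim.metrics_table <- function(x) dim(x$values)
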