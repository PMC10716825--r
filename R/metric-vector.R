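#' Validate a named metric vector
#'
#' A metric vector is a named numeric vector: names identify metrics, values
#' are the metric scores (the ray lengths of the polar projection). All
#' scoring functions in the package funnel their input through this check.
#'
#' @param x a named numeric vector.
#' @param allow_single if `FALSE` (default) at least one value is required;
#'   the polygon-degeneracy check (at least 3 metrics) happens later, at
#'   scoring time, because zero-weight exclusion can shrink the vector.
#' @return `x`, unchanged, invisibly usable; errors describe the offending
#'   metric by name.
#' @keywords internal
validate_metric_vector <- function(x, allow_single = TRUE) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("metric vector must be a numeric vector with at least one value",
         call. = FALSE)
  }
  nm <- names(x)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    stop("every metric value must carry a non-empty name", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate metric names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(x)
  if (any(bad)) {
    stop("non-finite metric values (missing cells are not implicit zeros): ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  if (any(x < 0)) {
    stop("negative metric values (ray lengths must be >= 0): ",
         paste(nm[x < 0], collapse = ", "),
         ". Rescale metrics that live on [-1, 1] (e.g. with rescale_unit()).",
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a weight vector
#'
#' Weights are a named numeric vector mapping metric names to non-negative
#' multipliers. Names must be a subset of the metric names they will be
#' applied to; that containment is checked in [apply_weights()].
#'
#' @param w named numeric vector of weights, or `NULL` (no weighting).
#' @keywords internal
validate_weight_vector <- function(w) {
  if (is.null(w)) return(invisible(NULL))
  if (is.list(w)) w <- unlist(w)
  if (length(w) == 0L) return(invisible(stats::setNames(numeric(0), character(0))))
  if (!is.numeric(w)) stop("weights must be numeric", call. = FALSE)
  nm <- names(w)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    stop("every weight must carry a metric name", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate weight names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(w))) {
    stop("non-finite weights: ", paste(nm[!is.finite(w)], collapse = ", "),
         call. = FALSE)
  }
  if (any(w < 0)) {
    stop("weights must be >= 0; negative weight for: ",
         paste(nm[w < 0], collapse = ", "), call. = FALSE)
  }
  invisible(w)
}

#' Rescale a metric from [-1, 1] to [0, 1]
#'
#' Convenience for metrics such as the Matthews correlation coefficient that
#' natively take values in \[-1, 1\]: the polar projection needs non-negative
#' ray lengths on a shared scale.
#'
#' @param x numeric values in \[-1, 1\].
#' @return `(x + 1) / 2`.
#' @export
#' @examples
#' rescale_unit(c(-1, 0, 1))
rescale_unit <- function(x) {
  if (any(is.finite(x) & (x < -1 | x > 1))) {
    stop("rescale_unit() expects values in [-1, 1]", call. = FALSE)
  }
  (x + 1) / 2
}
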