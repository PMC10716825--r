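sniff_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

resolve_delimiter <- function(delimiter, path) {
  switch(match.arg(delimiter, c("auto", "comma", "tab")),
         auto = sniff_delimiter(path), comma = ",", tab = "\t")
}

#' Read a metrics table from delimited text
#'
#' Expects a header row of metric names, a first column of model names, and
#' numeric cells (dot decimal separator, regardless of locale). The column
#' order in the file becomes the ray order on the polar plane and is
#' preserved exactly.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter `"auto"` (default; sniffs a tab in the header),
#'   `"comma"`, or `"tab"`.
#' @param upper_bound declared metric upper bound stored on the table.
#' @return a [metrics_table()].
#' @export
read_metrics_table <- function(path, delimiter = "auto", upper_bound = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- resolve_delimiter(delimiter, path)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, na.strings = c("NA", ""),
                          encoding = "UTF-8")
  if (nrow(df) == 0L) stop("no models: file has a header but no rows",
                           call. = FALSE)
  if (ncol(df) < 2L) stop("expected a model-name column plus metric columns",
                          call. = FALSE)
  models <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop("non-numeric cell at model '",
           models[if (is.na(bad)) 1L else bad], "', metric '",
           names(vals)[j], "'", call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- models
  metrics_table(m, upper_bound = upper_bound)
}

#' Write a metrics table as delimited text
#'
#' Inverse of [read_metrics_table()]: numbers are written with 15
#' significant digits so a read/write round trip preserves values to well
#' below 1e-12, and row/column order byte-for-byte.
#'
#' @param table a [metrics_table()].
#' @param path output path.
#' @param delimiter `"comma"` (default) or `"tab"`.
#' @param model_column header for the first (model name) column.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path, delimiter = "comma",
                                model_column = "model") {
  table <- as_metrics_table(table)
  sep <- switch(match.arg(delimiter, c("comma", "tab")),
                comma = ",", tab = "\t")
  m <- table$values
  lines <- c(
    paste(c(model_column, colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i],
              formatC(m[i, ], format = "g", digits = 15)), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a weight mapping from JSON or YAML
#'
#' The file holds a flat mapping metric-name -> non-negative number. A zero
#' weight marks the metric for exclusion downstream; negative weights are
#' rejected here.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file (content is
#'   sniffed if the extension is unhelpful).
#' @return a named numeric weight vector (possibly empty = identity
#'   weighting).
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parsed <- if (ext == "json" || grepl("^\\s*\\{", raw)) {
    jsonlite::fromJSON(raw)
  } else {
    yaml::yaml.load(raw)
  }
  if (is.null(parsed) || length(parsed) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (!is.list(parsed) && is.null(names(parsed))) {
    stop("weight file must be a mapping metric-name -> number", call. = FALSE)
  }
  w <- vapply(parsed, function(v) {
    if (!is.numeric(v) || length(v) != 1L) {
      stop("non-numeric weight value", call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  validate_weight_vector(w)
  w
}

#' Read a predictions file
#'
#' A delimited file with a header and columns `y_true`, `y_pred` and
#' optionally `y_score`, one row per instance.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter `"auto"`, `"comma"`, or `"tab"`.
#' @param positive_label passed to [prediction_set()].
#' @return a [prediction_set()].
#' @export
read_predictions <- function(path, delimiter = "auto", positive_label = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- resolve_delimiter(delimiter, path)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("y_true", "y_pred") %in% names(df)) &&
      !all(c("y_true", "y_score") %in% names(df))) {
    stop("predictions file needs columns y_true and y_pred (and/or y_score)",
         call. = FALSE)
  }
  prediction_set(
    y_true = df$y_true,
    y_pred = if ("y_pred" %in% names(df)) df$y_pred,
    y_score = if ("y_score" %in% names(df)) df$y_score,
    positive_label = positive_label
  )
}

#' Write a prediction set as CSV
#'
#' @param preds a [prediction_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  stopifnot(inherits(preds, "prediction_set"))
  df <- data.frame(y_true = preds$y_true)
  if (!is.null(preds$y_pred)) df$y_pred <- preds$y_pred
  if (!is.null(preds$y_score)) df$y_score <- preds$y_score
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ranking report as CSV
#'
#' Serialises the per-model columns of a [compare_rankings()] report
#' (`model`, `mlcps`, `mlcps_normalized`, `sd`, `rank_mlcps`, `rank_sd`,
#' `effective_metrics`, plus the cross-table columns when present).
#'
#' @param report a `ranking_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking_report <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
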