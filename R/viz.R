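#' Vertex data for a radar (polar) plot
#'
#' Returns the exact numbers handed to the plotting layer: one row per
#' model/metric pair with the ray angle and the (weighted) radius, plus a
#' repeated first vertex per model so the polygon closes. Rays are laid out
#' counter-clockwise from angle 0 in table column order.
#'
#' @param table a [metrics_table()] (or coercible).
#' @param weights optional weights (zero-weight metrics vanish from the
#'   plot, as from the score).
#' @param max_models overlaying too many polygons is unreadable; tables
#'   with more rows than this are truncated to the top rows with a warning
#'   (default 8).
#' @return a tibble with columns `model`, `metric`, `angle`, `radius`,
#'   `x`, `y` (Cartesian), and `closing` (logical: the repeated vertex).
#' @export
radar_plot_data <- function(table, weights = NULL, max_models = 8L) {
  table <- as_metrics_table(table)
  m <- table$values
  if (nrow(m) > max_models) {
    warning("showing only the first ", max_models, " of ", nrow(m),
            " models", call. = FALSE)
    m <- m[seq_len(max_models), , drop = FALSE]
  }
  rows <- lapply(rownames(m), function(model) {
    d <- apply_weights(m[model, ], weights)
    n <- length(d)
    ang <- (seq_len(n) - 1L) * compute_angle(n)
    idx <- c(seq_len(n), 1L)
    tibble::tibble(
      model = model,
      metric = names(d)[idx],
      angle = c(ang, ang[1L])[seq_len(n + 1L)],
      radius = unname(d[idx]),
      closing = c(rep(FALSE, n), TRUE)
    )
  })
  out <- do.call(rbind, rows)
  out$x <- out$radius * cos(out$angle)
  out$y <- out$radius * sin(out$angle)
  out
}

#' Bar-chart data for score ranking
#'
#' Models sorted by score, descending, with the rank in brackets appended
#' to the label (ties share the minimum rank).
#'
#' @param report a `ranking_report` from [compare_rankings()].
#' @param normalized plot `mlcps_normalized` instead of the raw area.
#' @return a tibble with `model`, `label` (e.g. `"svm [1]"`), `height`,
#'   `rank`, ordered by rank.
#' @export
bar_plot_data <- function(report, normalized = FALSE) {
  stopifnot(is.data.frame(report))
  h <- if (normalized) report$mlcps_normalized else report$mlcps
  ord <- order(report$rank_mlcps, report$model)
  tibble::tibble(
    model = report$model[ord],
    label = sprintf("%s [%d]", report$model[ord], report$rank_mlcps[ord]),
    height = h[ord],
    rank = report$rank_mlcps[ord]
  )
}

#' Dual-axis data comparing metric SD with the cumulative score
#'
#' Bars are the per-model SD of raw metric scores, ordered ascending
#' left-to-right (smallest SD first); the overlaid point series is the
#' cumulative performance score on a secondary axis. Disagreement between
#' bar order and point heights is the phenomenon of interest: a uniformly
#' mediocre model earns a low SD but also a low score.
#'
#' @param report a `ranking_report`.
#' @return a tibble ordered by ascending SD with `model`, `sd`, `mlcps`,
#'   `rank_sd`, `rank_mlcps`, and `mlcps_scaled` (score linearly mapped to
#'   the SD axis for overlay; the scaling factor is attribute
#'   `"axis_scale"`).
#' @export
sd_comparison_data <- function(report) {
  stopifnot(is.data.frame(report))
  ord <- order(report$rank_sd, report$model)
  out <- tibble::tibble(
    model = report$model[ord],
    sd = report$sd[ord],
    mlcps = report$mlcps[ord],
    rank_sd = report$rank_sd[ord],
    rank_mlcps = report$rank_mlcps[ord]
  )
  scale <- if (max(out$mlcps) > 0) max(out$sd) / max(out$mlcps) else 1
  if (scale == 0) scale <- 1
  out$mlcps_scaled <- out$mlcps * scale
  attr(out, "axis_scale") <- scale
  out
}

build_plot <- function(kind, data, title, include_values = FALSE) {
  switch(kind,
    radar = {
      ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y,
                                         group = .data$model,
                                         colour = .data$model,
                                         fill = .data$model)) +
        ggplot2::geom_polygon(alpha = 0.15) +
        ggplot2::geom_point(data = data[!data$closing, ]) +
        ggplot2::coord_equal() +
        ggplot2::labs(title = title, x = NULL, y = NULL) +
        ggplot2::theme_minimal()
    },
    bar = {
      p <- ggplot2::ggplot(data, ggplot2::aes(
        x = stats::reorder(.data$label, .data$rank),
        y = .data$height)) +
        ggplot2::geom_col(fill = "#4878a8") +
        ggplot2::labs(title = title, x = NULL,
                      y = "cumulative performance score") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      if (include_values) {
        p <- p + ggplot2::geom_text(
          ggplot2::aes(label = sprintf("%.3f", .data$height)),
          vjust = 1.5, colour = "white", size = 3)
      }
      p
    },
    sd_comparison = {
      scale <- attr(data, "axis_scale")
      ggplot2::ggplot(data, ggplot2::aes(
        x = stats::reorder(.data$model, .data$rank_sd))) +
        ggplot2::geom_col(ggplot2::aes(y = .data$sd), fill = "grey70") +
        ggplot2::geom_point(ggplot2::aes(y = .data$mlcps_scaled),
                            colour = "#c0392b", size = 2) +
        ggplot2::geom_line(ggplot2::aes(y = .data$mlcps_scaled, group = 1),
                           colour = "#c0392b") +
        ggplot2::scale_y_continuous(
          name = "SD of metric scores",
          sec.axis = ggplot2::sec_axis(~ . / scale,
                                       name = "cumulative performance score")) +
        ggplot2::labs(title = title, x = NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    },
    stop("unknown plot kind: ", kind, call. = FALSE)
  )
}

#' Render a plot to file
#'
#' Three kinds mirror the usual presentation of these analyses: `"radar"`
#' (per-model polygons on a shared polar frame, from [radar_plot_data()]),
#' `"bar"` (models sorted by score with bracketed ranks, from
#' [bar_plot_data()]) and `"sd_comparison"` (SD bars ascending with the
#' score overlaid on a secondary axis, from [sd_comparison_data()]).
#' The file is written atomically: to a temporary sibling first, then
#' renamed into place, so a failed render leaves no partial output.
#'
#' @param results for `"radar"` a [metrics_table()]; for the other kinds a
#'   `ranking_report` from [compare_rankings()].
#' @param kind `"radar"`, `"bar"` or `"sd_comparison"`.
#' @param path output file; format from `format` or the extension.
#' @param format `"png"`, `"svg"` or `"pdf"` (default: from extension).
#' @param title plot title.
#' @param include_values print the numeric score inside each bar.
#' @param weights optional weights (radar only).
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_plot <- function(results, kind = c("radar", "bar", "sd_comparison"),
                        path, format = NULL, title = NULL,
                        include_values = TRUE, weights = NULL,
                        width = 7, height = 5) {
  kind <- match.arg(kind)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("png", "svg", "pdf")) {
    stop("unsupported plot format: '", format,
         "' (use png, svg or pdf)", call. = FALSE)
  }
  if (is.null(title)) title <- kind
  data <- switch(kind,
    radar = radar_plot_data(results, weights = weights),
    bar = bar_plot_data(results),
    sd_comparison = sd_comparison_data(results)
  )
  if (nrow(data) == 0L) stop("nothing to plot: empty results", call. = FALSE)
  p <- build_plot(kind, data, title, include_values)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", format))
  dev <- switch(format, png = grDevices::png,
                svg = grDevices::svg, pdf = grDevices::pdf)
  if (format == "png") {
    dev(tmp, width = width, height = height, units = "in", res = 150)
  } else {
    dev(tmp, width = width, height = height)
  }
  ok <- FALSE
  tryCatch({
    print(p)
    ok <- TRUE
  }, finally = {
    grDevices::dev.off()
    if (!ok && file.exists(tmp)) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
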