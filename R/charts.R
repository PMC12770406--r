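#' Read a measurement table from CSV
#'
#' The table carries one row per case: `case_id`, `ga_weeks` (gestational
#' age, 16-40), `field_strength` (0.55 or 3.0 tesla), the biometry columns
#' (`cervical_length_mm`, `inlet_diameter_mm`, `outlet_diameter_mm`) and
#' per-label volume columns (`canal_mm3`, `inner_stroma_mm3`,
#' `outer_stroma_mm3`, `cyst_mm3`, `canal_total_mm3`). Additional columns
#' (e.g. maternal covariates) are carried through untouched.
#'
#' @param path CSV file path.
#' @return A validated `data.frame`.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurement_table(tab)
  tab
}

validate_measurement_table <- function(tab) {
  required <- c("case_id", "ga_weeks")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("measurement table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab$ga_weeks < 16 | tab$ga_weeks > 40, na.rm = TRUE)) {
    stop("ga_weeks outside the supported 16-40 week range", call. = FALSE)
  }
  if ("field_strength" %in% names(tab) &&
      !all(tab$field_strength %in% c(0.55, 3.0) | is.na(tab$field_strength))) {
    stop("field_strength must be 0.55 or 3.0", call. = FALSE)
  }
  key <- paste(tab$case_id, tab$ga_weeks)
  if (anyDuplicated(key)) {
    stop("duplicate case_id at the same timepoint", call. = FALSE)
  }
  measure_cols <- intersect(
    c("cervical_length_mm", "inlet_diameter_mm", "outlet_diameter_mm",
      "canal_mm3", "inner_stroma_mm3", "outer_stroma_mm3", "canal_total_mm3"),
    names(tab)
  )
  for (cl in measure_cols) {
    if (any(tab[[cl]] <= 0, na.rm = TRUE)) {
      stop("non-positive values in measurement column ", cl, call. = FALSE)
    }
  }
  invisible(tab)
}

#' Fit a gestational-age trend with empirical centile bands
#'
#' Least-squares polynomial of gestational age for one metric, with 5th /
#' 50th / 95th centile bands obtained by offsetting the fitted curve by
#' the empirical residual quantiles (no distributional assumption). The
#' constant offsets guarantee centile monotonicity across the whole
#' fitted range.
#'
#' @param table A measurement table (see [read_measurement_table()]).
#' @param metric Column name of the metric to model.
#' @param degree Polynomial degree (1 or 2).
#' @return An object of class `trend_model`.
#' @export
fit_trend <- function(table, metric, degree = 1L) {
  if (!metric %in% names(table)) {
    stop("metric column not found: ", metric, call. = FALSE)
  }
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2", call. = FALSE)
  keep <- is.finite(table[[metric]]) & is.finite(table$ga_weeks)
  ga <- table$ga_weeks[keep]
  y <- table[[metric]][keep]
  if (length(y) < 10) {
    stop("need at least 10 rows with the metric present", call. = FALSE)
  }
  if (stats::var(ga) == 0) stop("gestational age is constant", call. = FALSE)

  fit <- stats::lm(y ~ stats::poly(ga, degree, raw = TRUE))
  coefficients <- unname(stats::coef(fit))
  residuals <- unname(stats::resid(fit))
  offsets <- stats::quantile(residuals, c(0.05, 0.5, 0.95), names = FALSE)

  structure(
    list(metric = metric, degree = as.integer(degree),
         coefficients = coefficients,
         centile_offsets = c(p5 = offsets[1], p50 = offsets[2], p95 = offsets[3]),
         ga_range = range(ga), n = length(y),
         slope_sign = sign(coefficients[2])),
    class = "trend_model"
  )
}

#' Evaluate a fitted trend model
#'
#' @param model A [fit_trend()] result.
#' @param ga Gestational ages (weeks) at which to evaluate.
#' @param centile `"mean"` for the fitted curve, or `"p5"`, `"p50"`,
#'   `"p95"` for a centile curve.
#' @return Numeric vector of metric values.
#' @export
evaluate_trend <- function(model, ga, centile = c("mean", "p5", "p50", "p95")) {
  stopifnot(inherits(model, "trend_model"))
  centile <- match.arg(centile)
  y <- outer(ga, 0:model$degree, `^`) %*% model$coefficients
  y <- as.numeric(y)
  if (centile != "mean") y <- y + model$centile_offsets[[centile]]
  y
}

#' @export
print.trend_model <- function(x, ...) {
  cat("<trend_model> ", x$metric, " ~ GA (degree ", x$degree, ", n = ", x$n,
      ")\n  coefficients: ", paste(signif(x$coefficients, 5), collapse = ", "),
      "\n  centile offsets (p5/p50/p95): ",
      paste(signif(x$centile_offsets, 4), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Export normative charts and centile tables
#'
#' For each fitted model, writes a scatter + trend + centile-band figure
#' (points coloured by field strength) and a CSV of the centile curves
#' sampled at 0.5-week steps over the fitted gestational-age range.
#'
#' @param models List of [fit_trend()] results.
#' @param table The measurement table the models were fitted on.
#' @param out_dir Output directory (created if missing).
#' @param step Gestational-age sampling step in weeks for the centile CSV.
#' @param format Figure format, `"png"` or `"svg"`.
#' @return Invisibly, a list with `figures` and `csv` file paths.
#' @export
export_charts <- function(models, table, out_dir, step = 0.5,
                          format = c("png", "svg")) {
  format <- match.arg(format)
  if (inherits(models, "trend_model")) models <- list(models)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }

  figures <- character(0)
  csvs <- character(0)
  for (model in models) {
    ga <- seq(model$ga_range[1], model$ga_range[2], by = step)
    centiles <- data.frame(
      ga = ga,
      p5 = evaluate_trend(model, ga, "p5"),
      p50 = evaluate_trend(model, ga, "p50"),
      p95 = evaluate_trend(model, ga, "p95")
    )
    csv_path <- file.path(out_dir, paste0("centiles_", model$metric, ".csv"))
    utils::write.csv(centiles, csv_path, row.names = FALSE)
    csvs <- c(csvs, csv_path)

    fig_path <- file.path(out_dir, paste0("chart_", model$metric, ".", format))
    dat <- table[is.finite(table[[model$metric]]), ]
    dat$field <- if ("field_strength" %in% names(dat)) {
      factor(dat$field_strength)
    } else {
      factor("unknown")
    }
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ga_weeks,
                                           y = .data[[model$metric]])) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$field), alpha = 0.6) +
      ggplot2::geom_line(data = centiles,
                         ggplot2::aes(x = .data$ga, y = .data$p50),
                         linewidth = 0.9, inherit.aes = FALSE) +
      ggplot2::geom_line(data = centiles,
                         ggplot2::aes(x = .data$ga, y = .data$p5),
                         linetype = "dashed", inherit.aes = FALSE) +
      ggplot2::geom_line(data = centiles,
                         ggplot2::aes(x = .data$ga, y = .data$p95),
                         linetype = "dashed", inherit.aes = FALSE) +
      ggplot2::labs(x = "Gestational age (weeks)", y = model$metric,
                    colour = "Field (T)",
                    title = paste0(model$metric, " normative chart")) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(fig_path, p, width = 6, height = 4.5, dpi = 150)
    figures <- c(figures, fig_path)
  }
  invisible(list(figures = figures, csv = csvs))
}
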