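#' Control reference interval for a metric
#'
#' The default is the t-based 95% confidence interval of the control mean,
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)` — the band shaded per metric in a
#' control-referenced dot plot. A population reference band
#' (`mean +/- z * SD`) is available as `type = "reference"`.
#'
#' @param values Control measurements (one per tooth or patient).
#' @param level Confidence level.
#' @param type `"ci_mean"` (default) or `"reference"`.
#' @param metric Optional metric label.
#' @return Object of class `reference_interval`.
#' @export
reference_interval <- function(values, level = 0.95,
                               type = c("ci_mean", "reference"),
                               metric = NA_character_) {
  type <- match.arg(type)
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 2L) stop("at least 2 control values are required", call. = FALSE)
  m <- mean(v)
  s <- sd(v)
  a <- 1 - (1 - level) / 2
  half <- if (type == "ci_mean") qt(a, n - 1L) * s / sqrt(n) else qnorm(a) * s
  structure(list(metric = metric, n = n, mean = m, sd = s,
                 ci_low = m - half, ci_high = m + half,
                 level = level, type = type),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("%s%s interval (n = %d controls): mean %.4g, SD %.4g, [%.4g, %.4g]\n",
              if (is.na(x$metric)) "" else paste0(x$metric, ": "),
              if (x$type == "ci_mean") sprintf("%g%% CI of mean", 100 * x$level)
              else sprintf("%g%% reference", 100 * x$level),
              x$n, x$mean, x$sd, x$ci_low, x$ci_high))
  invisible(x)
}

#' Classify values against a control interval
#'
#' Strict comparison against the band edges; values on an edge count as
#' within.
#'
#' @param value Numeric vector.
#' @param interval A [reference_interval()].
#' @return Factor with levels `below`, `within`, `above`.
#' @export
classify_within_limits <- function(value, interval) {
  stopifnot(inherits(interval, "reference_interval"))
  out <- ifelse(value < interval$ci_low, "below",
                ifelse(value > interval$ci_high, "above", "within"))
  factor(out, levels = c("below", "within", "above"))
}

#' Fold change of case over control means
#'
#' @param case_mean,control_mean Group means; `control_mean` must be positive.
#' @return `case_mean / control_mean`.
#' @export
fold_change <- function(case_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0)
    stop("control mean must be > 0 for a fold change; report the absolute difference instead",
         call. = FALSE)
  case_mean / control_mean
}

#' Percent change of case relative to control
#'
#' @param case_mean,control_mean Group means; `control_mean` must be nonzero.
#' @return `100 * (case_mean - control_mean) / control_mean`.
#' @export
percent_change <- function(case_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean == 0)
    stop("control mean must be nonzero for a percent change", call. = FALSE)
  100 * (case_mean - control_mean) / control_mean
}

#' Assemble and validate a long-format cohort table
#'
#' @param data A `data.frame` with columns `patient`, `tooth`, `group`
#'   (`"case"`/`"control"`), `metric`, `value`; one value per tooth x metric.
#' @return The validated table, classed `cohort_table`.
#' @export
cohort_table <- function(data) {
  need <- c("patient", "tooth", "group", "metric", "value")
  if (!all(need %in% names(data)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(data$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'", call. = FALSE)
  key <- paste(data$tooth, data$metric, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate tooth x metric entries", call. = FALSE)
  structure(as.data.frame(data), class = c("cohort_table", "data.frame"))
}

#' Control-referenced cohort report
#'
#' For every metric with at least two control teeth and one case tooth:
#' control mean, SD and interval ([reference_interval()]); classification of
#' each value against the control band ([classify_within_limits()]); and
#' case-vs-control fold and percent change. Metrics missing a group are
#' skipped with a warning. Values are per tooth by default (matching dot plots
#' of individual teeth); `aggregate = "patient"` first averages each patient's
#' teeth.
#'
#' @param table A [cohort_table()] (or plain data frame with its columns).
#' @param level,type Passed to [reference_interval()].
#' @param aggregate `"tooth"` or `"patient"`.
#' @return Object of class `cohort_report` with elements `summary` (one row
#'   per metric), `values` (per observation with classification) and
#'   `intervals`.
#' @export
cohort_report <- function(table, level = 0.95,
                          type = c("ci_mean", "reference"),
                          aggregate = c("tooth", "patient")) {
  type <- match.arg(type)
  aggregate <- match.arg(aggregate)
  tb <- cohort_table(as.data.frame(table))
  if (aggregate == "patient") {
    tb <- stats::aggregate(value ~ patient + group + metric, data = tb,
                           FUN = mean)
    tb$tooth <- tb$patient
    tb <- cohort_table(tb[, c("patient", "tooth", "group", "metric", "value")])
  }
  metrics <- unique(tb$metric)
  srows <- list()
  vrows <- list()
  intervals <- list()
  for (mt in metrics) {
    sub <- tb[tb$metric == mt & is.finite(tb$value), , drop = FALSE]
    ctrl <- sub$value[sub$group == "control"]
    case <- sub$value[sub$group == "case"]
    if (length(ctrl) < 2L || length(case) < 1L) {
      warning(sprintf("metric '%s' skipped: needs >= 2 control and >= 1 case values",
                      mt))
      next
    }
    ri <- reference_interval(ctrl, level = level, type = type, metric = mt)
    intervals[[mt]] <- ri
    fc <- tryCatch(fold_change(mean(case), ri$mean), error = function(e) NA_real_)
    pc <- tryCatch(percent_change(mean(case), ri$mean),
                   error = function(e) NA_real_)
    srows[[mt]] <- data.frame(
      metric = mt, n_control = ri$n, control_mean = ri$mean,
      control_sd = ri$sd, ci_low = ri$ci_low, ci_high = ri$ci_high,
      n_case = length(case), case_mean = mean(case),
      case_sd = if (length(case) > 1L) sd(case) else NA_real_,
      fold_change = fc, percent_change = pc)
    sub$classification <- classify_within_limits(sub$value, ri)
    vrows[[mt]] <- sub
  }
  structure(list(summary = do.call(rbind, c(srows, list(make.row.names = FALSE))),
                 values = do.call(rbind, c(vrows, list(make.row.names = FALSE))),
                 intervals = intervals, level = level, type = type,
                 aggregate = aggregate),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report (%g%% %s, per %s): %d metrics\n",
              100 * x$level,
              if (x$type == "ci_mean") "CI of control mean" else "reference band",
              x$aggregate, nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Plot one metric of a cohort report
#'
#' Dot plot of per-tooth values by group with the control band shaded, the
#' standard presentation for small control-referenced cohorts.
#'
#' @param x A `cohort_report`.
#' @param metric Metric to plot (default: first).
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.cohort_report <- function(x, metric = NULL, ...) {
  if (is.null(metric)) metric <- x$summary$metric[1]
  ri <- x$intervals[[metric]]
  v <- x$values[x$values$metric == metric, , drop = FALSE]
  grp <- as.integer(factor(v$group, levels = c("control", "case")))
  pats <- factor(v$patient)
  cols <- grDevices::hcl.colors(max(3L, nlevels(pats)), "Dark 3")[as.integer(pats)]
  ylim <- range(c(v$value, ri$ci_low, ri$ci_high))
  plot(NA, xlim = c(0.5, 2.5), ylim = ylim, xaxt = "n",
       xlab = "", ylab = metric, main = metric)
  rect(0.5, ri$ci_low, 2.5, ri$ci_high,
       col = adjustcolor("grey60", 0.4), border = NA)
  segments(0.5, ri$mean, 2.5, ri$mean, lty = 2, col = "grey30")
  set_jitter <- (seq_along(grp) %% 5 - 2) * 0.04
  points(grp + set_jitter, v$value, pch = 19, col = cols)
  axis(1, at = 1:2, labels = c("control", "case"))
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Writes `summary.csv`, `values.csv` and one PNG dot plot per metric.
#'
#' @param report A [cohort_report()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(report$values, file.path(dir, "values.csv"), row.names = FALSE)
  for (mt in report$summary$metric) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", mt)
    png(file.path(dir, paste0(safe, ".png")), width = 600, height = 500)
    plot(report, metric = mt)
    dev.off()
  }
  invisible(dir)
}
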