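# Longitudinal aggregation: per-object CSV export, per-condition/day
# summaries of the mesenchymal score, normalization to the control
# baseline, and pairwise Student's t-tests.

measurement_columns <- c("experiment", "spheroid_id", "condition", "day",
                         "object_id", "area", "perimeter",
                         "convex_hull_area", "solidity", "form_factor",
                         "major_axis_length", "centroid_row", "centroid_col",
                         "mesenchymal_score")

#' Export a measurement table to CSV
#'
#' Writes an RFC-4180 CSV with a header, stable column order and numeric
#' values at 6 significant digits.
#'
#' @param table Measurement data.frame (one row per object).
#' @param path Output path.
#' @param allow_empty Permit writing a header-only file.
#' @return Number of data rows written, invisibly.
#' @export
export_csv <- function(table, path, allow_empty = TRUE) {
  if (nrow(table) == 0L && !allow_empty)
    stop("refusing to write an empty measurement table")
  cols <- intersect(measurement_columns, names(table))
  cols <- c(cols, setdiff(names(table), cols))
  out <- table[, cols, drop = FALSE]
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(nrow(out))
}

# One mesenchymal score per spheroid per day: objects within a spheroid are
# averaged first, so the spheroid is the replication unit downstream.
spheroid_scores <- function(table) {
  need <- c("condition", "day", "spheroid_id", "mesenchymal_score")
  miss <- need[!need %in% names(table)]
  if (length(miss)) stop("table lacks columns: ", paste(miss, collapse = ", "))
  bad <- is.na(table$condition) | is.na(table$day)
  if (any(bad))
    stop("rows with missing condition/day: ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  stats::aggregate(mesenchymal_score ~ condition + day + spheroid_id,
                   data = table, FUN = mean)
}

#' Summarize mesenchymal scores per condition and day
#'
#' Multiple objects of one spheroid are first averaged within the spheroid;
#' the summary then reports, per (condition, day): the number of spheroids,
#' the arithmetic mean and the sample standard deviation of the
#' per-spheroid scores.
#'
#' @param table Measurement data.frame with `condition`, `day`,
#'   `spheroid_id`, `mesenchymal_score`.
#' @return Data.frame of class `condition_summary` with columns
#'   `condition`, `day`, `n`, `mean_ms`, `sd_ms`.
#' @export
summarize_scores <- function(table) {
  ss <- spheroid_scores(table)
  agg <- stats::aggregate(mesenchymal_score ~ condition + day, data = ss,
                          FUN = function(x) c(n = length(x), mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(condition = agg$condition, day = agg$day,
                    n = as.integer(agg$mesenchymal_score[, "n"]),
                    mean_ms = agg$mesenchymal_score[, "mean"],
                    sd_ms = agg$mesenchymal_score[, "sd"],
                    stringsAsFactors = FALSE)
  out$sd_ms[is.na(out$sd_ms)] <- 0
  out <- out[order(out$condition, out$day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Normalize condition summaries to a control baseline
#'
#' Divides every per-condition/day mean score by the control condition's
#' mean at the baseline day, so the control baseline maps to exactly 1.
#'
#' @param summaries Output of [summarize_scores()].
#' @param control Control condition name (e.g. `"BSA"`).
#' @param baseline_day Baseline day (e.g. `1`).
#' @return `summaries` with an added `normalized_mean_ms` column.
#' @export
normalize_to_control <- function(summaries, control, baseline_day) {
  i <- summaries$condition == control & summaries$day == baseline_day
  if (!any(i)) stop("no summary for control '", control, "' at day ",
                    baseline_day)
  base <- summaries$mean_ms[i][1L]
  if (!is.finite(base) || base <= 0)
    stop("control baseline mean is not positive: ", base)
  summaries$normalized_mean_ms <- summaries$mean_ms / base
  summaries
}

#' Compare two conditions at one day by Student's t-test
#'
#' Two-sided two-sample t-test on per-spheroid mesenchymal scores, pooled
#' (equal) variance by default as in a classical Student's t-test; set
#' `welch = TRUE` for the Welch form. Significance is flagged at p <= 0.05.
#'
#' @param table Measurement data.frame.
#' @param condition_a,condition_b Condition names.
#' @param day Day to compare at.
#' @param welch Use Welch's unequal-variance form.
#' @param alpha Significance level for the reported flag.
#' @return List with `statistic`, `p_value`, `n_a`, `n_b`, `significant`.
#' @export
compare_conditions <- function(table, condition_a, condition_b, day,
                               welch = FALSE, alpha = 0.05) {
  ss <- spheroid_scores(table)
  xa <- ss$mesenchymal_score[ss$condition == condition_a & ss$day == day]
  xb <- ss$mesenchymal_score[ss$condition == condition_b & ss$day == day]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("need >= 2 spheroid scores per group (got ", length(xa), " and ",
         length(xb), ")")
  if (stats::var(xa) == 0 && stats::var(xb) == 0) {
    # degenerate zero-variance groups: t.test refuses; the pooled form has
    # t = 0 (p = 1) for equal means and +-Inf (p = 0) otherwise
    d <- mean(xa) - mean(xb)
    tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
               p.value = if (d == 0) 1 else 0)
  } else {
    tt <- stats::t.test(xa, xb, var.equal = !welch)
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n_a = length(xa), n_b = length(xb),
       significant = tt$p.value <= alpha)
}

#' All per-day comparisons against a control condition
#'
#' Runs [compare_conditions()] of every non-control condition against the
#' control at every day where both groups have at least two spheroids.
#' Optionally adds Benjamini-Hochberg adjusted p-values (off by default;
#' raw per-test significance is the reporting convention here).
#'
#' @param table Measurement data.frame.
#' @param control Control condition name.
#' @param welch Use Welch's form.
#' @param fdr Add a BH-adjusted `p_adjusted` column.
#' @return Data.frame with one row per (condition, day) comparison.
#' @export
compare_all_to_control <- function(table, control, welch = FALSE, fdr = FALSE) {
  ss <- spheroid_scores(table)
  conds <- setdiff(unique(ss$condition), control)
  days <- sort(unique(ss$day))
  rows <- list()
  for (cond in conds) for (d in days) {
    na <- sum(ss$condition == cond & ss$day == d)
    nb <- sum(ss$condition == control & ss$day == d)
    if (na < 2L || nb < 2L) next
    r <- compare_conditions(table, cond, control, d, welch = welch)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, control = control, day = d,
      t_statistic = r$statistic, p_value = r$p_value,
      n_condition = r$n_a, n_control = r$n_b,
      significant = r$significant, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), control = character(),
               day = integer(), t_statistic = double(), p_value = double(),
               n_condition = integer(), n_control = integer(),
               significant = logical())
  if (fdr && nrow(out)) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
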