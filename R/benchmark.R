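#' Donor metric table
#'
#' The long-format container for everything the benchmarking layer consumes:
#' one row per raw observation (a cell's spectral metric, a flow event's
#' channel value, a well's beta-gal percentage) keyed by donor, passage label
#' and metric name. Summary means/sds/counts are derived from it, and the raw
#' values are retained because the Welch tests need them.
#'
#' @param values data frame with columns `donor`, `passage` (`"E"`/`"S"`),
#'   `metric` (character) and `value` (finite numeric).
#' @return A `"donor_metric_table"` data frame.
#' @export
donor_metric_table <- function(values) {
  values <- as.data.frame(values)
  need <- c("donor", "passage", "metric", "value")
  if (!all(need %in% names(values)))
    stop("donor metric table needs columns donor, passage, metric, value")
  if (!all(values$passage %in% c("E", "S")))
    stop("passage labels must be 'E' or 'S'")
  if (!all(is.finite(values$value))) stop("metric values must be finite")
  values <- values[, need]
  class(values) <- c("donor_metric_table", "data.frame")
  values
}

#' Benchmark candidate senescence metrics against the standard
#'
#' The statistical layer of the workflow. For every metric in the table it
#' computes, per donor, the S/E fold difference of sample means and a
#' one-tailed Welch test on the raw values (direction fixed a priori as
#' senescent > early); per metric, the fold-difference range over donors; and
#' the Spearman correlation of the metric's per-(donor, passage) means
#' against the benchmark metric's values over the same points (both E and S
#' points enter jointly, one point per donor-passage). Donors missing an E or
#' S row for a metric are excluded from that metric with a warning.
#'
#' @param table a [donor_metric_table()].
#' @param benchmark_metric name of the reference metric (default
#'   `"bgal_pct"`, the beta-galactosidase positive percentage); it must be
#'   present for every (donor, passage) that any other metric covers.
#' @return A `"benchmark_report"`: list with `summary` (per metric, donor,
#'   passage: mean/sd/n), `folds`, `fold_ranges`, `welch`, `spearman` data
#'   frames and `benchmark_metric`.
#' @export
build_report <- function(table, benchmark_metric = "bgal_pct") {
  stopifnot(inherits(table, "donor_metric_table"))
  if (!benchmark_metric %in% table$metric)
    stop(sprintf("benchmark metric '%s' not present in the table",
                 benchmark_metric))
  agg <- stats::aggregate(value ~ metric + donor + passage, table,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1) stats::sd(v) else 0,
                                        n = length(v)))
  summary_df <- data.frame(metric = agg$metric, donor = agg$donor,
                           passage = agg$passage,
                           mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                           n = agg$value[, "n"], row.names = NULL)

  bench_pts <- summary_df[summary_df$metric == benchmark_metric,
                          c("donor", "passage", "mean")]
  names(bench_pts)[3] <- "bench"

  metrics <- unique(summary_df$metric)
  folds <- welch <- spearman <- NULL
  fold_ranges <- NULL
  for (m in metrics) {
    sm <- summary_df[summary_df$metric == m, ]
    donors <- unique(sm$donor)
    complete <- donors[vapply(donors, function(d)
      all(c("E", "S") %in% sm$passage[sm$donor == d]), TRUE)]
    if (length(complete) < length(donors))
      warning(sprintf("metric '%s': donor(s) %s lack an E or S row; excluded",
                      m, paste(setdiff(donors, complete), collapse = ", ")))
    for (d in complete) {
      e_mean <- sm$mean[sm$donor == d & sm$passage == "E"]
      s_mean <- sm$mean[sm$donor == d & sm$passage == "S"]
      folds <- rbind(folds, data.frame(
        metric = m, donor = d, fold = fold_difference(e_mean, s_mean)))
      ev <- table$value[table$metric == m & table$donor == d &
                          table$passage == "E"]
      sv <- table$value[table$metric == m & table$donor == d &
                          table$passage == "S"]
      if (length(ev) >= 2L && length(sv) >= 2L) {
        wt <- welch_one_tailed(ev, sv)
        welch <- rbind(welch, data.frame(
          metric = m, donor = d, t = wt$t, df = wt$df, p = wt$p,
          stars = wt$stars))
      }
    }
    if (!is.null(folds)) {
      fm <- folds$fold[folds$metric == m]
      if (length(fm))
        fold_ranges <- rbind(fold_ranges, data.frame(
          metric = m, fold_min = min(fm), fold_max = max(fm)))
    }
    # Spearman of this metric's (donor, passage) means vs the standard
    pts <- merge(sm[sm$donor %in% complete, c("donor", "passage", "mean")],
                 bench_pts, by = c("donor", "passage"))
    if (nrow(pts) >= 3L) {
      sp <- suppressWarnings(spearman_cor(pts$mean, pts$bench))
      spearman <- rbind(spearman, data.frame(
        metric = m, r = sp$r, p = sp$p, n = sp$n, method = sp$method))
    }
  }
  structure(list(summary = summary_df, folds = folds,
                 fold_ranges = fold_ranges, welch = welch,
                 spearman = spearman, benchmark_metric = benchmark_metric),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Senescence metric benchmark report\n")
  cat(sprintf("  standard: %s\n\n", x$benchmark_metric))
  cat("Fold-difference ranges (S/E, min-max over donors):\n")
  for (i in seq_len(nrow(x$fold_ranges)))
    cat(sprintf("  %-18s %.3f - %.3f\n", x$fold_ranges$metric[i],
                x$fold_ranges$fold_min[i], x$fold_ranges$fold_max[i]))
  if (!is.null(x$welch)) {
    sig <- stats::aggregate(p ~ metric, x$welch, function(p) mean(p <= 0.05))
    cat("\nWelch one-tailed tests (fraction of donors significant at 0.05):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %-18s %.2f\n", sig$metric[i], sig$p[i]))
  }
  if (!is.null(x$spearman)) {
    cat(sprintf("\nSpearman correlation vs %s:\n", x$benchmark_metric))
    for (i in seq_len(nrow(x$spearman)))
      cat(sprintf("  %-18s r = %6.3f  p = %.4g  (n = %d, %s)\n",
                  x$spearman$metric[i], x$spearman$r[i], x$spearman$p[i],
                  x$spearman$n[i], x$spearman$method[i]))
  }
  invisible(x)
}
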