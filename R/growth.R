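#' Population doublings
#'
#' One passage's population doubling is `log2(harvested / seeded)`: the
#' number of times the culture doubled between seeding and harvest.
#'
#' @param seeded,harvested positive cell counts (vectorized).
#' @return Numeric PD value(s).
#' @examples
#' population_doubling(1e5, 1e6)  # log2(10) ~ 3.32
#' @export
population_doubling <- function(seeded, harvested) {
  if (any(seeded <= 0) || any(harvested <= 0))
    stop("seeded and harvested counts must be positive")
  log2(harvested / seeded)
}

#' Build a growth curve from per-passage culture records
#'
#' Adds the derived columns the passage-classification rules need: per-passage
#' population doublings (`pd`), their cumulative sum (`cpd`) and the doubling
#' rate per day (`pd_rate`).
#'
#' @param records data frame with columns `passage` (index), `seeded`,
#'   `harvested` (positive counts) and `days` (> 0, days in culture for that
#'   passage).
#' @return A `"growth_curve"` data frame with the derived columns appended.
#' @export
growth_curve <- function(records) {
  records <- as.data.frame(records)
  need <- c("passage", "seeded", "harvested", "days")
  if (!all(need %in% names(records)))
    stop("growth records need columns passage, seeded, harvested, days")
  if (any(records$days <= 0)) stop("days in culture must be positive")
  records <- records[order(records$passage), , drop = FALSE]
  records$pd <- population_doubling(records$seeded, records$harvested)
  records$cpd <- cumsum(records$pd)
  records$pd_rate <- records$pd / records$days
  rownames(records) <- NULL
  class(records) <- c("growth_curve", "data.frame")
  records
}

#' Classify the early and senescent passage of a growth curve
#'
#' Early passage (E) is the passage whose cumulative population doubling is
#' closest to `early_target_cpd` (default 6); a tie is broken to the earlier
#' passage. The senescent passage (S) is the first passage satisfying the
#' chosen growth-arrest rule:
#' \describe{
#'   \item{`"lt1pd_7d"` (default)}{the culture achieved less than 1
#'     population doubling in 7 days, i.e. `pd_rate < 1/7`;}
#'   \item{`"no_doubling_14d"`}{the culture failed to double in two weeks,
#'     i.e. `pd_rate < 1/14`.}
#' }
#' Days are the per-passage days in culture recorded in the curve.
#'
#' @param curve a [growth_curve()].
#' @param early_target_cpd target cumulative PD for the early passage.
#' @param senescent_rule which growth-arrest rule defines S.
#' @return A list with `early` and `senescent` passage indices (`senescent`
#'   is `NA` — with a warning — when no passage satisfies the rule), plus
#'   the matching `early_cpd`.
#' @export
classify_passages <- function(curve, early_target_cpd = 6,
                              senescent_rule = c("lt1pd_7d",
                                                 "no_doubling_14d")) {
  stopifnot(inherits(curve, "growth_curve"))
  if (nrow(curve) < 2L) stop("growth curve needs at least two passages")
  senescent_rule <- match.arg(senescent_rule)
  e_idx <- which.min(abs(curve$cpd - early_target_cpd))  # first = earlier on tie
  thr <- switch(senescent_rule, lt1pd_7d = 1 / 7, no_doubling_14d = 1 / 14)
  hit <- which(curve$pd_rate < thr)
  if (length(hit)) {
    s_pass <- curve$passage[hit[1L]]
  } else {
    warning("no passage satisfies the senescence rule; S undefined")
    s_pass <- NA_integer_
  }
  list(early = curve$passage[e_idx], senescent = s_pass,
       early_cpd = curve$cpd[e_idx], rule = senescent_rule)
}

#' Percentage of beta-galactosidase positive cells
#'
#' The benchmark-standard senescence readout: blue-stained (positive) cells
#' as a percentage of all cells counted in a well. Counting fewer than 200
#' cells triggers an undercount warning, reflecting the counting rule the
#' assay is scored under.
#'
#' @param positive,total non-negative integer counts with
#'   `0 <= positive <= total`, `total >= 1`.
#' @return Percentage in `[0, 100]`, with attribute `undercounted` set to
#'   `TRUE` (plus a warning) when `total < 200`.
#' @examples
#' bgal_percentage(50, 200)  # 25
#' @export
bgal_percentage <- function(positive, total) {
  if (length(positive) != 1L || length(total) != 1L)
    stop("bgal_percentage takes scalar counts")
  if (total < 1) stop("total count must be >= 1")
  if (positive < 0 || positive > total)
    stop("positive count must lie in [0, total]")
  pct <- 100 * positive / total
  under <- total < 200
  if (under)
    warning(sprintf("undercounted: only %d cells counted (fewer than 200)",
                    as.integer(total)))
  structure(pct, undercounted = under)
}

#' Read / write the growth and beta-gal CSV dialects
#'
#' Growth CSV: `passage,seeded,harvested,days`. Beta-gal CSV:
#' `well,positive,total`.
#'
#' @param path file path.
#' @return `read_growth_csv()` returns a [growth_curve()];
#'   `read_bgal_csv()` a data frame of counts; writers return `path`
#'   invisibly.
#' @export
read_growth_csv <- function(path) growth_curve(utils::read.csv(path))

#' @rdname read_growth_csv
#' @param curve a [growth_curve()].
#' @export
write_growth_csv <- function(curve, path) {
  utils::write.csv(curve[, c("passage", "seeded", "harvested", "days")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_growth_csv
#' @export
read_bgal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("well", "positive", "total") %in% names(df)))
    stop("beta-gal CSV needs columns well, positive, total")
  df
}

#' @rdname read_growth_csv
#' @param counts data frame with columns `well`, `positive`, `total`.
#' @export
write_bgal_csv <- function(counts, path) {
  utils::write.csv(counts[, c("well", "positive", "total")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
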