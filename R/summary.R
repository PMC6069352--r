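#' Median and interquartile range
#'
#' Median uses the midpoint convention (mean of the central pair for even
#' n); quartiles use linear interpolation between order statistics
#' (`quantile()` type 7), the convention documented for the package's
#' benchmark tables.
#'
#' @param values non-empty numeric vector of night counts.
#' @param type quartile convention passed to [stats::quantile()].
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4))  # median 2.5
median_iqr <- function(values, type = 7) {
  if (length(values) == 0) abort("median_iqr needs a non-empty vector")
  q <- unname(quantile(values, c(0.25, 0.75), type = type, names = FALSE))
  c(median = median(values), q1 = q[1], q3 = q[2])
}

#' Percentage, rounded half-up to one decimal
#'
#' @param numerator,denominator counts, `numerator <= denominator`,
#'   `denominator > 0`.
#' @return percentage with one decimal.
#' @export
#' @examples
#' rate_percent(9151, 24354)  # 37.6
rate_percent <- function(numerator, denominator) {
  if (any(denominator == 0)) abort("rate_percent: zero denominator")
  if (any(numerator > denominator)) {
    abort("rate_percent: numerator exceeds denominator")
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Benchmark table of a-LOS components
#'
#' Aggregates linked episodes into the benchmark grid: for each resection
#' group, one row per non-empty access class (laparoscopic, open, converted)
#' plus a group total, followed by a combined-liver block and a grand-total
#' block. Each row reports n, median index LOS, the transfer rate and the
#' median transfer stay (over transferred cases only), the readmission rate
#' and the median readmission stay (over readmitted cases only), and the
#' median (i.q.r.) a-LOS. Percentages are rounded half-up to one decimal.
#'
#' @param episodes tibble from [link_episodes()] (needs `group`, `access`,
#'   `index_los`, `transferred`, `transfer_nights`, `readmitted`,
#'   `readmission_nights`, `alos`).
#' @param type quartile convention for [median_iqr()].
#' @return tibble of benchmark rows in fixed reporting order.
#' @export
summarize_cohort <- function(episodes, type = 7) {
  if (nrow(episodes) == 0) abort("summarize_cohort needs a non-empty cohort")
  cell <- function(df, group_label, access_label) {
    if (nrow(df) == 0) return(NULL)
    mi <- median_iqr(df$index_los, type = type)
    ma <- median_iqr(df$alos, type = type)
    tr <- df$transfer_nights[df$transferred]
    re <- df$readmission_nights[df$readmitted]
    tibble::tibble(
      group = group_label, access = access_label, n = nrow(df),
      median_index_los = mi[["median"]],
      pct_transferred = rate_percent(sum(df$transferred), nrow(df)),
      median_transfer_los = if (length(tr) > 0) median(tr) else NA_real_,
      pct_readmitted = rate_percent(sum(df$readmitted), nrow(df)),
      median_readmit_los = if (length(re) > 0) median(re) else NA_real_,
      alos_median = ma[["median"]], alos_q1 = ma[["q1"]], alos_q3 = ma[["q3"]]
    )
  }
  block <- function(df, group_label) {
    dplyr::bind_rows(
      purrr::map(ACCESS_LEVELS,
                 ~ cell(df[df$access == .x, , drop = FALSE], group_label, .x)),
      cell(df, group_label, "total")
    )
  }
  out <- dplyr::bind_rows(
    purrr::map(BENCHMARK_GROUPS,
               ~ block(episodes[episodes$group == .x, , drop = FALSE], .x)),
    block(episodes[episodes$group %in% c("major_liver", "minor_liver"), ,
                   drop = FALSE], "liver_combined"),
    block(episodes, "all")
  )
  out
}

#' Hospital nights added by aggregation
#'
#' How much longer the aggregated stay is than the conventional index stay:
#' the absolute difference of the medians (nights) and the relative increase
#' in percent (rounded half-up to one decimal).
#'
#' @param alos_median median a-LOS (nights).
#' @param index_median median index LOS (nights); must be positive.
#' @return named numeric vector `c(added_nights, relative_increase_pct)`.
#' @export
#' @examples
#' added_days(14, 9)  # 5 nights, 55.6%
added_days <- function(alos_median, index_median) {
  if (any(index_median <= 0)) abort("added_days: index median must be positive")
  c(added_nights = alos_median - index_median,
    relative_increase_pct =
      round_half_up(100 * (alos_median - index_median) / index_median, 1))
}

#' Hospitals exceeding yearly volume thresholds
#'
#' For each benchmark group, counts the distinct index hospitals with
#' strictly more than each threshold number of cases operated in the given
#' calendar year -- a simple measure of centralisation and volume provision.
#'
#' @param cases cohort tibble ([extract_cohort()]).
#' @param year calendar year of surgery dates to count.
#' @param thresholds positive integer thresholds.
#' @return tibble: `group`, `threshold`, `n_hospitals`.
#' @export
hospital_volume_summary <- function(cases, year, thresholds = c(10, 20)) {
  if (any(thresholds <= 0)) abort("thresholds must be positive")
  in_year <- cases[format(cases$surgery_date, "%Y") == as.character(year), ,
                   drop = FALSE]
  vols <- in_year |>
    dplyr::count(.data$group, .data$hospital_id, name = "volume")
  grid <- tidyr::expand_grid(group = BENCHMARK_GROUPS, threshold = thresholds)
  grid$n_hospitals <- purrr::map2_int(grid$group, grid$threshold, function(g, t) {
    sum(vols$volume[vols$group == g] > t)
  })
  grid
}

#' Box-and-whisker statistics for a-LOS plots
#'
#' Median, quartiles and mean, with the upper whisker at
#' `q3 + 1.5 * (q3 - q1)` and the lower whisker at the smallest observed
#' value at or above `q1 - 1.5 * (q3 - q1)`. Input values are a-LOS and
#' hence already capped at 30 nights, which skews the means.
#'
#' @param values non-empty numeric vector (a-LOS nights).
#' @param type quartile convention for [median_iqr()].
#' @return named list: `median`, `q1`, `q3`, `mean`, `whisker_low`,
#'   `whisker_high`.
#' @export
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 100))
boxplot_stats <- function(values, type = 7) {
  if (length(values) == 0) abort("boxplot_stats needs a non-empty vector")
  m <- median_iqr(values, type = type)
  iqr <- m[["q3"]] - m[["q1"]]
  lo_fence <- m[["q1"]] - 1.5 * iqr
  list(
    median = m[["median"]], q1 = m[["q1"]], q3 = m[["q3"]],
    mean = mean(values),
    whisker_low = min(values[values >= lo_fence]),
    whisker_high = m[["q3"]] + 1.5 * iqr
  )
}

#' Per-group a-LOS box-plot statistics
#'
#' One row per benchmark group and access class, with converted cases pooled
#' into the open-access group (conversions are open operations for the
#' purpose of aggregate plotting).
#'
#' @inheritParams summarize_cohort
#' @return tibble: `group`, `access` (laparoscopic/open), `n`, and the
#'   [boxplot_stats()] fields.
#' @export
summarize_boxplots <- function(episodes, type = 7) {
  pooled <- episodes
  pooled$access[pooled$access == "converted"] <- "open"
  pooled |>
    dplyr::group_by(.data$group, .data$access) |>
    dplyr::summarise(
      n = dplyr::n(),
      stats = list(boxplot_stats(.data$alos, type = type)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("stats") |>
    dplyr::arrange(match(.data$group, BENCHMARK_GROUPS), .data$access)
}
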