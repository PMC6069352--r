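test_that("median and quartiles follow the documented conventions", {
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  expect_equal(median_iqr(c(1, 2, 3, 4))[["median"]], 2.5)
  expect_error(median_iqr(numeric(0)), "non-empty")
  # Monte-Carlo: samples from the calibrated pancreatoduodenectomy a-LOS
  # generator recover the configured median
  withr::with_seed(13, {
    d <- fit_night_distribution(14, 10, 21)
    x <- sample_nights(d, 200)
    expect_lte(abs(median_iqr(x)[["median"]] - 14), 1)
  })
})

test_that("percentages reproduce the printed-rate convention", {
  expect_equal(rate_percent(9151, 24354), 37.6)
  expect_equal(rate_percent(12499, 24354), 51.3)
  expect_equal(rate_percent(0, 10), 0)
  expect_error(rate_percent(1, 0), "zero denominator")
  expect_error(rate_percent(11, 10), "exceeds")
})

test_that("the benchmark grid aggregates groups, accesses and totals", {
  one <- tibble::tibble(
    group = "whipple", access = "open", index_los = 9L,
    transferred = FALSE, transfer_nights = 0L,
    readmitted = FALSE, readmission_nights = 0L, alos = 9L
  )
  bm <- summarize_cohort(one)
  row <- bm[bm$group == "whipple" & bm$access == "open", ]
  expect_equal(row$n, 1)
  expect_equal(row$pct_transferred, 0)
  expect_true(is.na(row$median_transfer_los))

  all_tr <- tibble::tibble(
    group = "colonic", access = rep(c("laparoscopic", "open"), each = 5),
    index_los = 4L, transferred = TRUE, transfer_nights = 5L,
    readmitted = FALSE, readmission_nights = 0L, alos = 9L
  )
  bm2 <- summarize_cohort(all_tr)
  expect_true(all(bm2$pct_transferred == 100))
  expect_equal(bm2$median_transfer_los[1], 5)

  # totals arithmetic on a simulated cohort
  gen <- generate_registry(default_config(cases_per_group = 40, seed = 17))
  ep <- link_episodes(extract_cohort(gen$admissions, load_codemap())$cases,
                      gen$admissions)
  bm3 <- summarize_cohort(ep)
  grand <- bm3[bm3$group == "all" & bm3$access == "total", ]
  group_totals <- bm3[bm3$access == "total" &
                        !bm3$group %in% c("all", "liver_combined"), ]
  expect_equal(grand$n, sum(group_totals$n))
  for (g in unique(group_totals$group)) {
    cells <- bm3[bm3$group == g & bm3$access != "total", ]
    expect_equal(sum(cells$n), group_totals$n[group_totals$group == g])
  }
  liver <- bm3[bm3$group == "liver_combined" & bm3$access == "total", ]
  expect_equal(liver$n, sum(group_totals$n[group_totals$group %in%
                                             c("major_liver", "minor_liver")]))
  # every percentage cell is reproducible from its own row's counts
  expect_true(all(bm3$pct_transferred >= 0 & bm3$pct_transferred <= 100))
  expect_true(all(bm3$alos_q1 <= bm3$alos_median &
                    bm3$alos_median <= bm3$alos_q3))
})

test_that("aggregation deltas match the worked examples", {
  expect_equal(added_days(14, 9),
               c(added_nights = 5, relative_increase_pct = 55.6))
  expect_equal(added_days(12, 8),
               c(added_nights = 4, relative_increase_pct = 50))
  expect_equal(added_days(7, 7),
               c(added_nights = 0, relative_increase_pct = 0))
  expect_error(added_days(5, 0), "positive")
})

test_that("hospital volume counts use a strict threshold", {
  cases <- tibble::tibble(
    group = "colonic",
    hospital_id = rep(c("H01", "H02", "H03"), times = c(5, 15, 25)),
    surgery_date = as.Date("2015-06-01")
  )
  v <- hospital_volume_summary(cases, 2015, thresholds = c(10, 30))
  expect_equal(v$n_hospitals[v$group == "colonic" & v$threshold == 10], 2L)
  expect_equal(v$n_hospitals[v$group == "colonic" & v$threshold == 30], 0L)
  # volumes in other years do not count
  cases$surgery_date <- as.Date("2014-06-01")
  v2 <- hospital_volume_summary(cases, 2015, thresholds = 10)
  expect_equal(sum(v2$n_hospitals), 0L)
  expect_error(hospital_volume_summary(cases, 2015, thresholds = 0), "positive")
})

test_that("hospital volumes round-trip through the generator", {
  # 32 colonic hospitals, enough cases that each exceeds 10 in the index year
  cfg <- default_config(cases_per_group = 0, seed = 23)
  cfg$groups$colonic$n_cases <- 32L * 11L * 5L * 3L  # ample margin per hospital-year
  gen <- generate_registry(cfg)
  cases <- extract_cohort(gen$admissions, load_codemap())$cases
  v <- hospital_volume_summary(cases, 2015, thresholds = 10)
  expect_equal(v$n_hospitals[v$group == "colonic" & v$threshold == 10], 32L)
})

test_that("box-plot statistics follow the whisker rules", {
  b <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(b$median, 3)
  expect_equal(b$whisker_high, b$q3 + 1.5 * (b$q3 - b$q1))
  expect_equal(b$whisker_low, 1)
  # degenerate spread
  b2 <- boxplot_stats(c(7, 7, 7))
  expect_equal(unlist(b2), c(median = 7, q1 = 7, q3 = 7, mean = 7,
                             whisker_low = 7, whisker_high = 7))
  # formula bounds on arbitrary data
  withr::with_seed(3, {
    for (i in 1:20) {
      x <- sample(0:30, sample(3:50, 1), replace = TRUE)
      b3 <- boxplot_stats(x)
      expect_gte(b3$whisker_low, min(x))
      expect_lte(b3$whisker_low, b3$q1)
      expect_gte(b3$whisker_high, b3$q3)
    }
  })
})

test_that("box-plot summaries pool converted cases into the open group", {
  ep <- tibble::tibble(
    group = "gastric",
    access = c("laparoscopic", "open", "converted", "open"),
    index_los = 5L, transferred = FALSE, transfer_nights = 0L,
    readmitted = FALSE, readmission_nights = 0L,
    alos = c(5L, 9L, 13L, 11L)
  )
  bp <- summarize_boxplots(ep)
  expect_setequal(bp$access, c("laparoscopic", "open"))
  expect_equal(bp$n[bp$access == "open"], 3L)
  expect_equal(bp$median[bp$access == "open"], 11)
})

test_that("cell medians and group rates are recovered on a calibrated simulation", {
  cfg <- default_config(cases_per_group = 2000, seed = 101)
  gen <- generate_registry(cfg)
  ex <- extract_cohort(gen$admissions, load_codemap())
  ep <- link_episodes(ex$cases, gen$admissions)
  bm <- summarize_cohort(ep)
  # index-LOS medians per well-filled access cell, within one night
  cal <- alosbench:::calibration_table()
  names(cal)[names(cal) == "n"] <- "n_cal"
  m <- merge(bm, cal, by = c("group", "access"))
  big <- m[m$n >= 500, ]
  expect_gte(nrow(big), 10)
  expect_true(all(abs(big$median_index_los - big$index_med) <= 1))
  # transfer/readmission rates per group (n = 2000), within 2.5 points of
  # the access-mixture expectation
  mixture <- function(g, what) {
    gp <- cfg$groups[[g]]
    100 * sum(vapply(names(gp$access_mix), function(a) {
      gp$access_mix[[a]] * gp$access[[a]][[what]]
    }, numeric(1)))
  }
  for (g in unique(cal$group)) {
    tot <- bm[bm$group == g & bm$access == "total", ]
    expect_equal(tot$n, 2000)
    expect_lte(abs(tot$pct_transferred - mixture(g, "transfer_prob")), 2.5)
    expect_lte(abs(tot$pct_readmitted - mixture(g, "readmit_prob")), 2.5)
  }
})
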