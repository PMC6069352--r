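stays <- function(...) {
  args <- list(...)
  tibble::tibble(
    patient_id = "P1",
    hospital_id = vapply(args, function(s) s[[1]], ""),
    admission_date = as.Date(vapply(args, function(s) s[[2]], "")),
    discharge_date = as.Date(vapply(args, function(s) s[[3]], ""))
  )
}

test_that("contiguous same-hospital stays merge into one interval", {
  m <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-05"),
                                    c("A", "2015-03-05", "2015-03-09")))
  expect_equal(nrow(m), 1)
  expect_equal(m$admission_date, as.Date("2015-03-01"))
  expect_equal(m$discharge_date, as.Date("2015-03-09"))

  # disjoint stays stay apart; a single stay is untouched
  m2 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-05"),
                                     c("A", "2015-03-07", "2015-03-09")))
  expect_equal(nrow(m2), 2)
  m3 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-05")))
  expect_equal(nrow(m3), 1)
  # different hospitals never merge even on the same dates
  m4 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-05"),
                                     c("B", "2015-03-05", "2015-03-09")))
  expect_equal(nrow(m4), 2)
})

test_that("index LOS is nights from surgery to first discharge or transfer", {
  case <- case_stub("2015-03-01", "A")
  m <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08")))
  expect_equal(compute_index_los(case, m), 7L)
  # day-case surgery
  m0 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-01")))
  expect_equal(compute_index_los(case, m0), 0L)
  # a within-hospital handover is folded into the index stay first
  m8 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-05"),
                                     c("A", "2015-03-05", "2015-03-09")))
  expect_equal(compute_index_los(case, m8), 8L)
  # surgery date outside every index-hospital stay errors
  expect_error(
    compute_index_los(case_stub("2015-06-01", "A"), m),
    "outside every stay"
  )
})

test_that("transfer stays are same-date handovers to another hospital", {
  case <- case_stub("2015-03-01", "A")
  m <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                    c("B", "2015-03-08", "2015-03-12")))
  tr <- find_transfer_stays(case, m)
  expect_equal(tr$hospital_id, "B")
  expect_equal(tr$nights_in_window, 4L)
  # admission the day after discharge is not a transfer
  m2 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                     c("B", "2015-03-09", "2015-03-12")))
  expect_equal(nrow(find_transfer_stays(case, m2)), 0)
  # chains are followed: A -> B -> C
  m3 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                     c("B", "2015-03-08", "2015-03-10"),
                                     c("C", "2015-03-10", "2015-03-13")))
  tr3 <- find_transfer_stays(case, m3)
  expect_equal(tr3$hospital_id, c("B", "C"))
  expect_equal(tr3$nights_in_window, c(2L, 3L))
})

test_that("readmissions need a full night out of hospital and a 30-day window", {
  case <- case_stub("2015-03-01", "A")
  m <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                    c("A", "2015-03-20", "2015-03-23")))
  re <- find_readmissions(case, m)
  expect_equal(nrow(re), 1)
  expect_equal(re$nights_in_window, 3L)
  # same-date same-hospital row merges into the index stay instead
  m2 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                     c("A", "2015-03-08", "2015-03-11")))
  expect_equal(nrow(find_readmissions(case, m2)), 0)
  expect_equal(compute_index_los(case, m2), 10L)
  # admission 35 days after surgery is outside the window
  m3 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                     c("B", "2015-04-05", "2015-04-09")))
  expect_equal(nrow(find_readmissions(case, m3)), 0)
  # a stay overlapping the transfer interval is not separated by a night
  m4 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                     c("B", "2015-03-08", "2015-03-14"),
                                     c("C", "2015-03-11", "2015-03-13")))
  expect_equal(nrow(find_readmissions(case, m4)), 0)
  # ... but one night after the transfer discharge qualifies
  m5 <- merge_contiguous_stays(stays(c("A", "2015-03-01", "2015-03-08"),
                                     c("B", "2015-03-08", "2015-03-14"),
                                     c("C", "2015-03-15", "2015-03-18")))
  expect_equal(find_readmissions(case, m5)$hospital_id, "C")
})

test_that("a-LOS adds non-overlapping components and caps at 30 nights", {
  case <- case_stub("2015-03-01", "A")
  s <- stays(c("A", "2015-03-01", "2015-03-08"),   # 7 index nights
             c("B", "2015-03-08", "2015-03-12"),   # 4 transfer nights
             c("A", "2015-03-20", "2015-03-23"))   # 3 readmission nights
  expect_equal(compute_alos(case, s), 14L)
  expect_equal(compute_alos(case, s), oracle_alos(s, "2015-03-01"))
  # continuous 45-night stay truncates at the window
  long <- stays(c("A", "2015-03-01", "2015-04-15"))
  expect_equal(compute_alos(case, long), 30L)
  # no transfers or readmissions: a-LOS = min(index LOS, 30)
  solo <- stays(c("A", "2015-03-01", "2015-03-06"))
  expect_equal(compute_alos(case, solo), 5L)
})

test_that("interval a-LOS equals the per-night occupancy oracle on random stay sets", {
  withr::with_seed(99, {
    for (i in 1:200) {
      x <- random_stay_set(extra = 4)
      case <- case_stub(x$surgery, x$index_hospital)
      alos <- compute_alos(case, x$stays)
      expect_identical(as.integer(alos), as.integer(oracle_alos(x$stays, x$surgery)))
      expect_gte(alos, 0L)
      expect_lte(alos, 30L)
      expect_gte(alos, min(x$index_los, 30L))
      # monotonicity: an added stay never decreases a-LOS
      start <- x$surgery + sample(-2:35, 1)
      more <- rbind(x$stays, tibble::tibble(
        patient_id = "P1", hospital_id = "H09",
        admission_date = start, discharge_date = start + sample(0:10, 1)
      ))
      expect_gte(compute_alos(case, more), alos)
    }
  })
})

test_that("full linkage agrees with the per-case functions and the oracle", {
  withr::with_seed(7, {
    for (i in 1:40) {
      x <- random_stay_set(extra = 4)
      reg <- x$stays
      reg$procedures <- ""
      reg$diagnoses <- ""
      case <- tibble::tibble(
        case_id = "c1", patient_id = "P1", surgery_date = x$surgery,
        hospital_id = x$index_hospital, group = "colonic", access = "open"
      )
      ep <- link_episodes(case, reg)
      m <- merge_contiguous_stays(x$stays)
      m$patient_id <- "P1"
      expect_equal(ep$index_los, compute_index_los(case, m))
      expect_equal(ep$n_transfers, nrow(find_transfer_stays(case, m)))
      expect_equal(ep$n_readmissions, nrow(find_readmissions(case, m)))
      expect_equal(ep$alos, as.integer(oracle_alos(x$stays, x$surgery)))
      expect_gte(ep$alos, min(ep$index_los, 30L))
    }
  })
})

test_that("with non-overlapping stays a-LOS decomposes into its components", {
  gen <- generate_registry(default_config(cases_per_group = 60, seed = 14))
  ex <- extract_cohort(gen$admissions, load_codemap())
  ep <- link_episodes(ex$cases, gen$admissions)
  expect_true(all(
    ep$alos == pmin(ep$index_los, 30L) + ep$transfer_nights +
      ep$readmission_nights
  ))
  expect_true(all(ep$alos >= 0 & ep$alos <= 30))
  expect_equal(ep$transferred, ep$n_transfers > 0)
  expect_equal(ep$readmitted, ep$n_readmissions > 0)
})
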