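#' Merge contiguous stays at the same hospital
#'
#' Transfers of care *within* an institution appear in administrative data
#' as back-to-back rows: a new admission at the same hospital on (or before)
#' the previous discharge date. Such rows are folded into one interval, so
#' within-hospital handovers count towards the index stay rather than as
#' transfers or readmissions.
#'
#' @param stays tibble of one patient's stays: `hospital_id`,
#'   `admission_date`, `discharge_date` (a `patient_id` column is allowed
#'   and preserved).
#' @return tibble of merged intervals, one row per maximal contiguous stay,
#'   sorted by hospital then admission date.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   hospital_id = "A",
#'   admission_date = as.Date(c("2015-03-01", "2015-03-05")),
#'   discharge_date = as.Date(c("2015-03-05", "2015-03-09"))
#' )
#' merge_contiguous_stays(s)
merge_contiguous_stays <- function(stays) {
  stays <- tibble::as_tibble(stays)
  if (!"patient_id" %in% names(stays)) stays$patient_id <- "."
  merged <- merge_stays_by_patient(stays)
  if (all(merged$patient_id == ".")) merged$patient_id <- NULL
  merged
}

## Vectorised contiguous-interval merge over (patient, hospital) groups.
merge_stays_by_patient <- function(stays) {
  stays |>
    dplyr::arrange(.data$patient_id, .data$hospital_id,
                   .data$admission_date, .data$discharge_date) |>
    dplyr::group_by(.data$patient_id, .data$hospital_id) |>
    dplyr::mutate(
      .new = .data$admission_date >
        dplyr::lag(cummax(as.integer(.data$discharge_date)),
                   default = -.Machine$integer.max),
      .grp = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$patient_id, .data$hospital_id, .data$.grp) |>
    dplyr::summarise(
      admission_date = min(.data$admission_date),
      discharge_date = max(.data$discharge_date),
      .groups = "drop"
    ) |>
    dplyr::select(-".grp")
}

## ---------------------------------------------------------------------
## Episode core. One patient's *merged* stays as parallel vectors --
## hospital ids `h`, admission/discharge as integer day offsets from the
## surgery date (`a`, `d`) -- plus the index hospital id. All linkage
## semantics live here; the exported per-case functions and the cohort-wide
## link_episodes() are wrappers.
## ---------------------------------------------------------------------
episode_core <- function(h, a, d, index_hospital) {
  ## index interval: the merged stay at the operating hospital containing
  ## day 0 (the surgery date)
  idx <- which(h == index_hospital & a <= 0L & d >= 0L)
  if (length(idx) == 0) {
    abort("surgery date lies outside every stay at the index hospital")
  }
  idx <- idx[1]
  index_los <- d[idx]

  ## transfer chain: same-date handovers to a new hospital, followed
  ## transitively; deterministic tie-break on hospital id
  used <- idx
  frontier <- d[idx]
  transfers <- integer(0)
  repeat {
    hit <- which(a == frontier & !seq_along(h) %in% used &
                   !h %in% h[used])
    if (length(hit) == 0) break
    nxt <- hit[order(h[hit])[1]]
    transfers <- c(transfers, nxt)
    used <- c(used, nxt)
    frontier <- d[nxt]
  }

  ## readmissions: any other stay admitted within day 30, at least one full
  ## night after every index/transfer interval begun by then
  episode_a <- a[used]
  episode_d <- d[used]
  cand <- setdiff(which(a <= 30L), used)
  re <- integer(0)
  for (i in cand) {
    begun <- episode_a <= a[i]
    if (any(begun) && a[i] >= max(episode_d[begun]) + 1L) re <- c(re, i)
  }
  re <- re[order(a[re], h[re])]

  ## a-LOS: union of occupied nights over all stays, clipped to nights 1..30
  alos <- occupied_union(pmax(a, 0L), pmin(d - 1L, 29L))

  list(
    index = idx, index_los = index_los,
    transfers = transfers, transfer_nights = clip30(a[transfers], d[transfers]),
    readmissions = re, readmission_nights = clip30(a[re], d[re]),
    alos = alos
  )
}

## nights of [a, d) (day offsets from surgery) inside the 30-night window
clip30 <- function(a, d) {
  pmax(pmin(d - 1L, 29L) - pmax(a, 0L) + 1L, 0L)
}

## length of the union of inclusive integer intervals [lo_i, hi_i]
occupied_union <- function(lo, hi) {
  keep <- hi >= lo
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0) return(0L)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- cummax(hi[o])
  total <- 0L
  run_lo <- lo[1]; run_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] > run_hi + 1L) {
      total <- total + run_hi - run_lo + 1L
      run_lo <- lo[i]
    }
    run_hi <- hi[i]
  }
  total + run_hi - run_lo + 1L
}

## Merge + core for one case given tibble inputs (shared by the exported
## per-case functions).
case_core <- function(case, merged_stays) {
  s <- as.Date(case$surgery_date)
  episode_core(
    merged_stays$hospital_id,
    as.integer(merged_stays$admission_date - s),
    as.integer(merged_stays$discharge_date - s),
    case$hospital_id
  )
}

stay_slice <- function(merged_stays, idx, nights) {
  out <- merged_stays[idx, c("hospital_id", "admission_date", "discharge_date")]
  out$nights_in_window <- as.integer(nights)
  tibble::as_tibble(out)
}

#' Index length of stay
#'
#' Nights from the date of surgery to first discharge or transfer from the
#' operating institution: the discharge date of the merged index-hospital
#' interval containing the surgery, minus the surgery date. Reported
#' untruncated. Same-date admission and discharge counts as 0 nights
#' (midnight census).
#'
#' @param case one row of a cohort tibble ([extract_cohort()]) or a list:
#'   needs `hospital_id` and `surgery_date`.
#' @param merged_stays the patient's merged stays
#'   ([merge_contiguous_stays()]).
#' @return integer nights.
#' @export
compute_index_los <- function(case, merged_stays) {
  as.integer(case_core(case, merged_stays)$index_los)
}

#' Find transfer stays
#'
#' A transfer stay is an admission to another hospital on the same calendar
#' date as discharge from the hospital performing the index procedure.
#' Chains are followed transitively: a further same-date handover from a
#' transfer hospital is also a transfer. Nights are clipped to the 30-night
#' window after surgery.
#'
#' @inheritParams compute_index_los
#' @return tibble of transfer stays in chain order: `hospital_id`,
#'   `admission_date`, `discharge_date`, `nights_in_window`.
#' @export
find_transfer_stays <- function(case, merged_stays) {
  core <- case_core(case, merged_stays)
  stay_slice(merged_stays, core$transfers, core$transfer_nights)
}

#' Find readmissions
#'
#' A readmission is an admission to any hospital within 30 days of the index
#' surgery (closed window), separated by at least one night out of hospital
#' from any index or transfer stay: the admission date must be at least one
#' day after the latest discharge among the index/transfer intervals already
#' begun by then (so a stay overlapping any such interval never qualifies).
#' Nights are clipped to the 30-night window; all readmissions are retained.
#'
#' @inheritParams compute_index_los
#' @param transfers ignored (accepted for call-site symmetry; transfers are
#'   recomputed from the merged stays).
#' @return tibble: `hospital_id`, `admission_date`, `discharge_date`,
#'   `nights_in_window`.
#' @export
find_readmissions <- function(case, merged_stays, transfers = NULL) {
  core <- case_core(case, merged_stays)
  stay_slice(merged_stays, core$readmissions, core$readmission_nights)
}

#' Aggregated length of stay (a-LOS)
#'
#' The number of distinct calendar nights, among the 30 nights following the
#' surgery date, on which the patient occupied *any* hospital bed. Counting
#' the union of occupied nights means overlapping records are never double
#' counted; with non-overlapping stays a-LOS equals clipped index plus
#' transfer plus readmission nights.
#'
#' @param case row or list with `surgery_date`.
#' @param stays all of the patient's stays (merged or raw; the union is the
#'   same).
#' @return integer in 0..30.
#' @export
compute_alos <- function(case, stays) {
  s <- as.Date(case$surgery_date)
  a <- as.integer(stays$admission_date - s)
  d <- as.integer(stays$discharge_date - s)
  as.integer(occupied_union(pmax(a, 0L), pmin(d - 1L, 29L)))
}

#' Link episodes of care for a cohort
#'
#' For every index case, merges the patient's stays
#' ([merge_contiguous_stays()]), computes the index LOS, follows same-date
#' transfer chains, identifies 30-day readmissions and computes the a-LOS
#' occupancy union.
#'
#' @param cases cohort tibble from [extract_cohort()].
#' @param admissions the full admission registry (all of the patients'
#'   stays, not only those with resection codes).
#' @return tibble (one row per case): `case_id`, `group`, `access`,
#'   `index_los`, `transferred`, `n_transfers`, `transfer_nights`,
#'   `readmitted`, `n_readmissions`, `readmission_nights`, `alos`.
#' @export
link_episodes <- function(cases, admissions) {
  admissions <- as_registry(admissions)
  if (nrow(cases) == 0) {
    return(tibble::tibble(
      case_id = character(), group = character(), access = character(),
      index_los = integer(), transferred = logical(), n_transfers = integer(),
      transfer_nights = integer(), readmitted = logical(),
      n_readmissions = integer(), readmission_nights = integer(),
      alos = integer()
    ))
  }
  stays <- admissions[admissions$patient_id %in% cases$patient_id,
                      c("patient_id", "hospital_id", "admission_date",
                        "discharge_date")]
  merged <- merge_stays_by_patient(stays)
  ## split to plain per-patient vectors once; per-case work is then pure
  ## integer arithmetic
  pid <- merged$patient_id
  h_all <- split(merged$hospital_id, pid)
  a_all <- split(as.integer(merged$admission_date), pid)
  d_all <- split(as.integer(merged$discharge_date), pid)

  n <- nrow(cases)
  index_los <- integer(n)
  n_transfers <- integer(n)
  transfer_nights <- integer(n)
  n_readmissions <- integer(n)
  readmission_nights <- integer(n)
  alos <- integer(n)
  surgery_int <- as.integer(cases$surgery_date)
  for (i in seq_len(n)) {
    p <- cases$patient_id[i]
    core <- episode_core(
      h_all[[p]], a_all[[p]] - surgery_int[i], d_all[[p]] - surgery_int[i],
      cases$hospital_id[i]
    )
    index_los[i] <- core$index_los
    n_transfers[i] <- length(core$transfers)
    transfer_nights[i] <- sum(core$transfer_nights)
    n_readmissions[i] <- length(core$readmissions)
    readmission_nights[i] <- sum(core$readmission_nights)
    alos[i] <- core$alos
  }
  tibble::tibble(
    case_id = cases$case_id, group = cases$group, access = cases$access,
    index_los = index_los,
    transferred = n_transfers > 0,
    n_transfers = n_transfers,
    transfer_nights = transfer_nights,
    readmitted = n_readmissions > 0,
    n_readmissions = n_readmissions,
    readmission_nights = readmission_nights,
    alos = alos
  )
}
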