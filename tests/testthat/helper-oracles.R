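# Shared fixtures and independent oracles.

# Build a registry tibble from compact stay descriptions.
# Each stay: list(p = patient, h = hospital, adm, dis, proc = "CODE@date;...",
# diag = "CODE@date;...")
make_registry <- function(...) {
  stays <- list(...)
  tibble::tibble(
    patient_id = vapply(stays, function(s) s$p, ""),
    hospital_id = vapply(stays, function(s) s$h, ""),
    admission_date = as.Date(vapply(stays, function(s) s$adm, "")),
    discharge_date = as.Date(vapply(stays, function(s) s$dis, "")),
    procedures = vapply(stays, function(s) s$proc %||% "", ""),
    diagnoses = vapply(stays, function(s) s$diag %||% "", "")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force a-LOS oracle: enumerate the 30 nights after surgery and count
# those on which any stay holds the patient (night n follows day
# surgery + n - 1; a stay [adm, dis) occupies the nights of days
# adm .. dis - 1).
oracle_alos <- function(stays, surgery_date) {
  s <- as.Date(surgery_date)
  sum(vapply(1:30, function(n) {
    day <- s + n - 1
    any(stays$admission_date <= day & day < stays$discharge_date)
  }, logical(1)))
}

# Random stay set for one synthetic patient: an index stay plus `extra`
# stays with arbitrary overlaps, same-date handovers and gaps.
random_stay_set <- function(extra = 3) {
  surgery <- as.Date("2015-03-01")
  index_los <- sample(0:20, 1)
  stays <- tibble::tibble(
    patient_id = "P1",
    hospital_id = "H01",
    admission_date = surgery - sample(0:1, 1),
    discharge_date = surgery + index_los
  )
  k <- sample(0:extra, 1)
  for (i in seq_len(k)) {
    start <- surgery + sample(-2:40, 1)
    stays <- rbind(stays, tibble::tibble(
      patient_id = "P1",
      hospital_id = sprintf("H%02d", sample(1:5, 1)),
      admission_date = start,
      discharge_date = start + sample(0:15, 1)
    ))
  }
  list(stays = stays, surgery = surgery, index_hospital = "H01",
       index_los = index_los)
}

# Case stub for the per-case linkage functions.
case_stub <- function(surgery, hospital = "H01") {
  list(case_id = "c", patient_id = "P1",
       surgery_date = as.Date(surgery), hospital_id = hospital)
}
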