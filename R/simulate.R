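#' Generate a synthetic admission registry with ground truth
#'
#' Simulates patient-level hospital admission records for digestive cancer
#' resections: for each case an index admission carrying the resection
#' procedure code(s) on the surgery date (converted cases carry one
#' laparoscopic and one open code), with the configured probability a
#' same-date transfer admission at another of the group's hospitals
#' (optionally chained to a second hospital), and with the configured
#' probability a later readmission separated by at least one night from the
#' index/transfer stays. Colonic cases carry a malignancy diagnosis near the
#' surgery date except for the configured noise fraction; reoperation and
#' same-date multi-organ secondary resections are injected as configured so
#' the exclusion filters can be exercised. Noise counts are deterministic
#' (`round(fraction * n)`), so extraction accounting is exact for a given
#' config.
#'
#' Deterministic given `config$seed`: the same config yields a byte-identical
#' registry.
#'
#' @param config a simulation config from [default_config()] or
#'   [national_cohort_config()].
#' @param codemap code map used to emit procedure/diagnosis codes.
#' @return list with `admissions` (registry tibble, see
#'   [admission-registry]) and `truth` (one row per generated candidate
#'   resection: case/patient ids, true group and access, true night counts,
#'   demographics, and `excluded_reason` -- `NA`, `"no_malignancy"`,
#'   `"secondary"` or `"reoperation"`).
#' @export
#' @examples
#' reg <- generate_registry(default_config(cases_per_group = 20, seed = 42))
#' head(reg$admissions)
#' table(reg$truth$group)
generate_registry <- function(config, codemap = load_codemap()) {
  validate_config(config)
  withr::with_seed(config$seed, generate_registry_impl(config, codemap))
}

## benchmark group -> (organ group, liver extent) for code lookup
group_organ <- function(g) {
  switch(g,
    whipple = c("pancreatoduodenal", "not_applicable"),
    major_liver = c("liver", "major"),
    minor_liver = c("liver", "minor"),
    c(g, "not_applicable")
  )
}

## codes in the map for one (benchmark group, access flag) cell
code_pool <- function(codemap, group, access_flag) {
  oe <- group_organ(group)
  p <- codemap$procedures
  p$code[p$organ_group == oe[1] & p$liver_extent == oe[2] &
           p$access == access_flag]
}

## diagnosis code emitted with each index admission (illustrative ICD-10
## stems; colonic malignancy must match the map's patterns)
GROUP_DIAGNOSIS <- c(
  oesophageal = "C15", gastric = "C16", whipple = "C25",
  distal_pancreatic = "C25", colonic = "C18", rectal = "C20",
  major_liver = "C22", minor_liver = "C22"
)

## uniform draw among 1..n_h excluding `idx` (community hospital 99 when
## there is no alternative)
other_hospital <- function(idx, n_h) {
  n_h <- rep_len(as.integer(n_h), length(idx))
  out <- rep(99L, length(idx))
  ok <- n_h >= 2L
  if (any(ok)) {
    draw <- as.integer(floor(runif(sum(ok)) * (n_h[ok] - 1L))) + 1L
    out[ok] <- ((idx[ok] - 1L + draw) %% n_h[ok]) + 1L
  }
  out
}

empty_registry <- function() {
  tibble::tibble(
    patient_id = character(), hospital_id = character(),
    admission_date = as.Date(character()), discharge_date = as.Date(character()),
    procedures = character(), diagnoses = character()
  )
}

empty_truth <- function() {
  tibble::tibble(
    case_id = character(), patient_id = character(), group = character(),
    access = character(), surgery_date = as.Date(character()),
    hospital_id = character(), age = numeric(), sex = character(),
    index_nights = integer(), transferred = logical(), n_transfers = integer(),
    transfer_nights = integer(), readmitted = logical(),
    readmit_day = integer(), readmit_nights = integer(), alos = integer(),
    excluded_reason = character()
  )
}

## nights a stay starting on post-surgery day `start` and lasting `los`
## nights contributes inside the 30-night window (occupied days start ..
## start+los-1, window days 0..29)
clip_nights <- function(start, los) {
  pmax(0L, pmin(start + los - 1L, 29L) - pmax(start, 0L) + 1L) * (los > 0L)
}

generate_registry_impl <- function(config, codemap) {
  ## ---- case frame: one row per primary case, grouped by (group, access)
  blocks <- list()
  for (g in BENCHMARK_GROUPS) {
    gp <- config$groups[[g]]
    if (gp$n_cases == 0) next
    n_by_access <- apportion(gp$n_cases, gp$access_mix)
    for (i in seq_along(gp$access_mix)) {
      if (n_by_access[i] == 0) next
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        group = g, access = names(gp$access_mix)[i],
        n_hospitals = gp$n_hospitals, .rows = n_by_access[i]
      )
    }
  }
  if (length(blocks) == 0) {
    return(list(admissions = empty_registry(), truth = empty_truth()))
  }
  cases <- dplyr::bind_rows(blocks)
  n <- nrow(cases)
  cases$case_id <- sprintf("C%06d", seq_len(n))
  cases$patient_id <- sprintf("P%06d", seq_len(n))

  ## ---- per-case draws, blockwise by (group, access) so each block uses
  ## its calibrated parameters
  cases$hosp_num <- NA_integer_
  cases$index_los <- NA_integer_
  cases$transferred <- FALSE
  cases$chain <- FALSE
  cases$t1_los <- NA_integer_
  cases$t2_los <- NA_integer_
  cases$readmit <- FALSE
  cases$readmit_los <- NA_integer_
  cases$code_open <- NA_character_
  cases$code_lap <- NA_character_

  key <- paste(cases$group, cases$access)
  for (k in unique(key)) {
    sel <- which(key == k)
    m <- length(sel)
    g <- cases$group[sel[1]]
    a <- cases$access[sel[1]]
    gp <- config$groups[[g]]
    ap <- gp$access[[a]]
    cases$hosp_num[sel] <- sample.int(gp$n_hospitals, m, replace = TRUE)
    d_index <- fit_night_distribution(ap$index_los[["median"]],
                                      ap$index_los[["q1"]],
                                      ap$index_los[["q3"]])
    cases$index_los[sel] <- sample_nights(d_index, m)
    cases$transferred[sel] <- runif(m) < ap$transfer_prob
    if (!is.null(ap$transfer_los)) {
      d_tr <- fit_night_distribution(ap$transfer_los[["median"]],
                                     ap$transfer_los[["q1"]],
                                     ap$transfer_los[["q3"]])
      cases$t1_los[sel] <- sample_nights(d_tr, m, min_nights = 1)
      cases$t2_los[sel] <- sample_nights(d_tr, m, min_nights = 1)
    } else {
      cases$transferred[sel] <- FALSE
    }
    cases$readmit[sel] <- runif(m) < ap$readmit_prob
    if (!is.null(ap$readmit_los)) {
      d_re <- fit_night_distribution(ap$readmit_los[["median"]],
                                     ap$readmit_los[["q1"]],
                                     ap$readmit_los[["q3"]])
      cases$readmit_los[sel] <- sample_nights(d_re, m, min_nights = 1)
    } else {
      cases$readmit[sel] <- FALSE
    }
    pool_open <- code_pool(codemap, g, "open")
    pool_lap <- code_pool(codemap, g, "laparoscopic")
    if (a %in% c("open", "converted")) {
      if (length(pool_open) == 0) abort(paste0("no open code for group ", g))
      cases$code_open[sel] <- pool_open[sample.int(length(pool_open), m, replace = TRUE)]
    }
    if (a %in% c("laparoscopic", "converted")) {
      if (length(pool_lap) == 0) abort(paste0("no laparoscopic code for group ", g))
      cases$code_lap[sel] <- pool_lap[sample.int(length(pool_lap), m, replace = TRUE)]
    }
    ## transfer chains need a third hospital
    cases$chain[sel] <- cases$transferred[sel] &
      gp$n_hospitals >= 3 &
      runif(m) < config$transfer_chain_prob
  }

  ## surgery dates: uniform, leaving room for the 30-day window
  span <- as.integer(diff(config$date_range))
  cases$surgery <- config$date_range[1] +
    (sample.int(span - 59L, n, replace = TRUE) - 1L)
  cases$preop <- rbinom(n, 1, 0.3)

  ## transfer destinations
  cases$dest1 <- NA_integer_
  cases$dest2 <- NA_integer_
  tr <- which(cases$transferred)
  cases$dest1[tr] <- other_hospital(cases$hosp_num[tr], cases$n_hospitals[tr])
  ch <- which(cases$chain)
  if (length(ch) > 0) {
    d2 <- other_hospital(cases$dest1[ch], cases$n_hospitals[ch])
    ## redraw where the second hop bounced back to the index hospital
    for (it in 1:50) {
      bad <- d2 == cases$hosp_num[ch]
      if (!any(bad)) break
      d2[bad] <- other_hospital(cases$dest1[ch][bad], cases$n_hospitals[ch][bad])
    }
    cases$dest2[ch] <- d2
  }

  ## readmission timing: at least one full night out of hospital after the
  ## last index/transfer discharge, within the 30-day window
  last_dis <- cases$index_los +
    ifelse(cases$transferred, cases$t1_los, 0L) +
    ifelse(cases$chain, cases$t2_los, 0L)
  lo <- last_dis + 2L
  cases$readmit <- cases$readmit & lo <= 30L
  cases$readmit_day <- NA_integer_
  re <- which(cases$readmit)
  if (length(re) > 0) {
    cases$readmit_day[re] <- lo[re] +
      floor(runif(length(re)) * (30L - lo[re] + 1L))
  }
  back_to_index <- runif(n) < 0.5
  cases$readmit_hosp <- ifelse(back_to_index, cases$hosp_num,
                               other_hospital(cases$hosp_num, cases$n_hospitals))

  ## demographics (ground truth only; the registry format carries no
  ## person-level covariates)
  dem <- config$demographics
  cases$age <- pmin(pmax(rnorm(n, dem$mean_age, dem$sd_age), 18), 100)
  cases$sex <- ifelse(runif(n) < dem$prop_male, "M", "F")

  ## diagnoses: every index admission carries an organ diagnosis code dated
  ## near surgery; the colonic no-malignancy noise cases get a benign code
  cases$diag_code <- GROUP_DIAGNOSIS[cases$group]
  cases$diag_offset <- sample.int(11L, n, replace = TRUE) - 6L   # -5..+5
  cases$no_malig <- FALSE
  colonic <- which(cases$group == "colonic")
  n_nomal <- round(config$noise$colonic_no_malignancy * length(colonic))
  if (n_nomal > 0) {
    pick <- sample(colonic, n_nomal)
    cases$no_malig[pick] <- TRUE
    cases$diag_code[pick] <- "D12"
  }

  ## same-date multi-organ noise: a lower-ranked (minor liver) secondary
  ## resection code on the surgery date of a non-liver case
  cases$multi <- FALSE
  elig_multi <- which(!cases$group %in% c("major_liver", "minor_liver") &
                        !cases$no_malig)
  n_multi <- round(config$noise$multiorgan * n)
  if (n_multi > length(elig_multi)) {
    abort("multiorgan noise fraction exceeds eligible cases")
  }
  if (n_multi > 0) cases$multi[sample(elig_multi, n_multi)] <- TRUE
  pool_liver_minor <- code_pool(codemap, "minor_liver", "open")
  cases$multi_code <- NA_character_
  mi <- which(cases$multi)
  if (length(mi) > 0) {
    cases$multi_code[mi] <-
      pool_liver_minor[sample.int(length(pool_liver_minor), length(mi), replace = TRUE)]
  }

  ## reoperation noise: a further resection of the same site 1-30 days
  ## after an (eligible, kept) case, in its own admission
  cases$reop <- FALSE
  elig_reop <- which(!cases$no_malig)
  n_reop <- round(config$noise$reoperation * n)
  if (n_reop > length(elig_reop)) {
    abort("reoperation noise fraction exceeds eligible cases")
  }
  if (n_reop > 0) cases$reop[sample(elig_reop, n_reop)] <- TRUE
  cases$reop_day <- NA_integer_
  ro <- which(cases$reop)
  if (length(ro) > 0) {
    cases$reop_day[ro] <- sample.int(30L, length(ro), replace = TRUE)
    ## same-site open code for the reoperation
    reop_pool_code <- character(length(ro))
    for (g in unique(cases$group[ro])) {
      pool <- code_pool(codemap, g, "open")
      gi <- which(cases$group[ro] == g)
      reop_pool_code[gi] <- pool[sample.int(length(pool), length(gi), replace = TRUE)]
    }
    cases$reop_code <- NA_character_
    cases$reop_code[ro] <- reop_pool_code
  } else {
    cases$reop_code <- NA_character_
  }

  ## unrelated admissions (stress-test for the occupancy union; default 0)
  n_unrel <- rpois(n, config$noise$unrelated_rate)

  ## ---- assemble admission rows
  hosp_id <- function(k) sprintf("H%02d", k)
  iso <- function(d) format(d, "%Y-%m-%d")

  surgery_s <- iso(cases$surgery)
  proc_index <- dplyr::case_when(
    cases$access == "open" ~ paste0(cases$code_open, "@", surgery_s),
    cases$access == "laparoscopic" ~ paste0(cases$code_lap, "@", surgery_s),
    TRUE ~ paste0(cases$code_lap, "@", surgery_s, ";",
                  cases$code_open, "@", surgery_s)
  )
  proc_index <- ifelse(cases$multi,
                       paste0(proc_index, ";", cases$multi_code, "@", surgery_s),
                       proc_index)
  diag_index <- paste0(cases$diag_code, "@",
                       iso(cases$surgery + cases$diag_offset))

  adm_index <- tibble::tibble(
    patient_id = cases$patient_id,
    hospital_id = hosp_id(cases$hosp_num),
    admission_date = cases$surgery - cases$preop,
    discharge_date = cases$surgery + cases$index_los,
    procedures = proc_index,
    diagnoses = diag_index
  )

  adm_tr1 <- {
    i <- which(cases$transferred)
    tibble::tibble(
      patient_id = cases$patient_id[i],
      hospital_id = hosp_id(cases$dest1[i]),
      admission_date = cases$surgery[i] + cases$index_los[i],
      discharge_date = cases$surgery[i] + cases$index_los[i] + cases$t1_los[i],
      procedures = "", diagnoses = ""
    )
  }
  adm_tr2 <- {
    i <- which(cases$chain)
    tibble::tibble(
      patient_id = cases$patient_id[i],
      hospital_id = hosp_id(cases$dest2[i]),
      admission_date = cases$surgery[i] + cases$index_los[i] + cases$t1_los[i],
      discharge_date = cases$surgery[i] + cases$index_los[i] + cases$t1_los[i] +
        cases$t2_los[i],
      procedures = "", diagnoses = ""
    )
  }
  adm_re <- {
    i <- which(cases$readmit)
    tibble::tibble(
      patient_id = cases$patient_id[i],
      hospital_id = hosp_id(cases$readmit_hosp[i]),
      admission_date = cases$surgery[i] + cases$readmit_day[i],
      discharge_date = cases$surgery[i] + cases$readmit_day[i] + cases$readmit_los[i],
      procedures = "", diagnoses = ""
    )
  }
  adm_reop <- if (!any(cases$reop)) empty_registry() else {
    i <- which(cases$reop)
    d <- cases$surgery[i] + cases$reop_day[i]
    tibble::tibble(
      patient_id = cases$patient_id[i],
      hospital_id = hosp_id(cases$hosp_num[i]),
      admission_date = d,
      discharge_date = d + 2L,
      procedures = paste0(cases$reop_code[i], "@", iso(d)),
      ## the reoperated colon carries a malignancy code at the reoperation
      ## too, so the diagnosis filter is not what removes it
      diagnoses = ifelse(cases$group[i] == "colonic",
                         paste0("C18@", iso(d)), "")
    )
  }
  adm_unrel <- {
    i <- rep(seq_len(n), n_unrel)
    if (length(i) > 0) {
      u <- sample.int(30L, length(i), replace = TRUE)
      tibble::tibble(
        patient_id = cases$patient_id[i],
        hospital_id = hosp_id(sample.int(40L, length(i), replace = TRUE)),
        admission_date = cases$surgery[i] + u,
        discharge_date = cases$surgery[i] + u + sample.int(3L, length(i), replace = TRUE),
        procedures = "",
        diagnoses = paste0("I10@", iso(cases$surgery[i] + u))
      )
    } else {
      empty_registry()
    }
  }

  admissions <- dplyr::bind_rows(adm_index, adm_tr1, adm_tr2, adm_re,
                                 adm_reop, adm_unrel)
  admissions <- dplyr::arrange(admissions, .data$patient_id,
                               .data$admission_date, .data$hospital_id)

  ## ---- ground truth
  t1_clip <- ifelse(cases$transferred,
                    clip_nights(cases$index_los, cases$t1_los), 0L)
  t2_clip <- ifelse(cases$chain,
                    clip_nights(cases$index_los + cases$t1_los, cases$t2_los), 0L)
  re_clip <- ifelse(cases$readmit,
                    clip_nights(cases$readmit_day, cases$readmit_los), 0L)
  truth <- tibble::tibble(
    case_id = cases$case_id,
    patient_id = cases$patient_id,
    group = cases$group,
    access = cases$access,
    surgery_date = cases$surgery,
    hospital_id = hosp_id(cases$hosp_num),
    age = cases$age,
    sex = cases$sex,
    index_nights = cases$index_los,
    transferred = cases$transferred,
    n_transfers = as.integer(cases$transferred) + as.integer(cases$chain),
    transfer_nights = as.integer(t1_clip + t2_clip),
    readmitted = cases$readmit,
    readmit_day = cases$readmit_day,
    readmit_nights = as.integer(re_clip),
    alos = as.integer(pmin(cases$index_los, 30L) + t1_clip + t2_clip + re_clip),
    excluded_reason = ifelse(cases$no_malig, "no_malignancy", NA_character_)
  )
  truth_secondary <- {
    i <- which(cases$multi)
    tibble::tibble(
      case_id = paste0(cases$case_id[i], "-S"),
      patient_id = cases$patient_id[i],
      group = "minor_liver", access = "open",
      surgery_date = cases$surgery[i],
      hospital_id = hosp_id(cases$hosp_num[i]),
      excluded_reason = "secondary"
    )
  }
  truth_reop <- {
    i <- which(cases$reop)
    tibble::tibble(
      case_id = paste0(cases$case_id[i], "-R"),
      patient_id = cases$patient_id[i],
      group = cases$group[i], access = "open",
      surgery_date = cases$surgery[i] + cases$reop_day[i],
      hospital_id = hosp_id(cases$hosp_num[i]),
      excluded_reason = "reoperation"
    )
  }
  truth <- dplyr::bind_rows(truth, truth_secondary, truth_reop)

  list(admissions = admissions, truth = truth)
}
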