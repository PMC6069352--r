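#' Classify surgical access from same-date procedure codes
#'
#' Access is assigned as open unless a designated laparoscopic resection
#' code was used; if both a laparoscopic and an open resection code are
#' present on the surgery date the operation is classed as converted
#' (laparoscopy converted to open).
#'
#' @param codes character vector of procedure codes recorded on the surgery
#'   date.
#' @param codemap a [load_codemap()] object.
#' @return `"open"`, `"laparoscopic"` or `"converted"`.
#' @export
#' @examples
#' cm <- load_codemap()
#' classify_access(c("JFB41", "JFB40"), cm)  # converted
classify_access <- function(codes, codemap) {
  stopifnot(inherits(codemap, "codemap"))
  p <- codemap$procedures
  acc <- p$access[match(codes, p$code)]
  acc <- acc[!is.na(acc)]
  if (length(acc) == 0) {
    abort("no resection codes on the surgery date")
  }
  has_lap <- any(acc == "laparoscopic")
  has_open <- any(acc == "open")
  if (has_lap && has_open) "converted"
  else if (has_lap) "laparoscopic"
  else "open"
}

#' Rank same-date resections by organ site
#'
#' When two organ sites are resected on the same date, the higher-ranked
#' site is kept and the other treated as a secondary resection. The ranking
#' (highest first) is: oesophageal, pancreatoduodenal, rectal, gastric,
#' distal pancreatic, colonic, liver.
#'
#' @param groups character vector (a set) of organ groups.
#' @return the highest-ranked organ group.
#' @export
#' @examples
#' rank_same_date(c("colonic", "rectal"))        # "rectal"
#' rank_same_date(c("liver", "distal_pancreatic"))
rank_same_date <- function(groups) {
  groups <- unique(groups)
  if (length(groups) == 0) abort("empty set of organ groups")
  r <- match(groups, ORGAN_RANKING)
  if (anyNA(r)) {
    abort(paste0("unknown organ group(s): ",
                 paste(groups[is.na(r)], collapse = ", ")))
  }
  ORGAN_RANKING[min(r)]
}

#' Colonic malignancy window filter
#'
#' A colonic resection is only included when a colonic malignancy diagnosis
#' was coded within 30 days before or after the resection (closed window,
#' calendar-day difference of at most 30).
#'
#' @param surgery_date the resection date.
#' @param diagnoses tibble of the patient's dated diagnoses (`code`, `date`).
#' @param codemap a [load_codemap()] object.
#' @return `TRUE` if a qualifying diagnosis exists.
#' @export
colonic_malignancy_filter <- function(surgery_date, diagnoses, codemap) {
  if (is.null(diagnoses) || nrow(diagnoses) == 0) return(FALSE)
  hit <- matches_malignancy(diagnoses$code, codemap)
  if (!any(hit)) return(FALSE)
  any(abs(as.integer(diagnoses$date[hit] - as.Date(surgery_date))) <= 30)
}

#' Exclude reoperations within 30 days of a kept resection
#'
#' Scanning one patient's candidate resections chronologically, a candidate
#' whose surgery date falls 1-30 days (closed window) after the surgery date
#' of an already-kept case is excluded as a reoperation. Excluded cases do
#' not themselves anchor further exclusions.
#'
#' @param candidates tibble of one patient's candidates with a
#'   `surgery_date` column, in any order.
#' @return list with `kept` and `excluded` tibbles (original columns,
#'   chronological order).
#' @export
exclude_reoperations <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(list(kept = candidates, excluded = candidates))
  }
  ord <- order(candidates$surgery_date)
  candidates <- candidates[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(candidates))
  kept_dates <- as.Date(character())
  for (i in seq_len(nrow(candidates))) {
    d <- candidates$surgery_date[i]
    if (length(kept_dates) > 0) {
      gap <- as.integer(d - kept_dates)
      if (any(gap >= 1 & gap <= 30)) {
        keep[i] <- FALSE
        next
      }
    }
    kept_dates <- c(kept_dates, d)
  }
  list(kept = candidates[keep, , drop = FALSE],
       excluded = candidates[!keep, , drop = FALSE])
}

#' Extract the analysis cohort from an admission registry
#'
#' Applies the inclusion/exclusion rules to raw admissions and returns the
#' analysed index cases plus a flow-chart style accounting report:
#'
#' 1. every distinct (patient, date, organ group) with a mapped resection
#'    code is a candidate resection; surgical access is classified from that
#'    group's codes on the surgery date, liver candidates are split into
#'    major/minor extent (major wins when codes of both extents co-occur);
#' 2. colonic candidates without a colonic malignancy diagnosis within +/-30
#'    days are excluded;
#' 3. when several candidates share a date, only the highest-ranked organ is
#'    kept ([rank_same_date()]); the rest are excluded as secondary
#'    resections;
#' 4. candidates 1-30 days after an already-kept case of the same patient
#'    are excluded as reoperations ([exclude_reoperations()]).
#'
#' @param admissions registry tibble (see [read_admissions()]).
#' @param codemap a [load_codemap()] object.
#' @return list with `cases` (tibble: `case_id`, `patient_id`,
#'   `surgery_date`, `hospital_id`, `group` -- one of the 8 benchmark
#'   groups -- `access`, `record` reference into `admissions`) ordered by
#'   patient then surgery date, and `report` (an `extraction_report` with
#'   `n_candidate_resections`, `n_colonic_excluded_no_malignancy`,
#'   `n_excluded_reoperation_or_secondary`, `n_final`).
#' @export
extract_cohort <- function(admissions, codemap) {
  stopifnot(inherits(codemap, "codemap"))
  proc <- procedures_long(admissions)
  proc <- dplyr::inner_join(proc, codemap$procedures, by = "code")

  if (nrow(proc) == 0) {
    report <- new_extraction_report(0L, 0L, 0L)
    return(list(cases = empty_cohort(), report = report))
  }

  ## one candidate per (patient, date, organ); deterministic tie-breaks on
  ## admission row then code string
  cand <- proc |>
    dplyr::arrange(.data$patient_id, .data$date, .data$organ_group,
                   .data$record, .data$code) |>
    dplyr::group_by(.data$patient_id, .data$date, .data$organ_group) |>
    dplyr::summarise(
      has_lap = any(.data$access == "laparoscopic"),
      has_open = any(.data$access == "open"),
      has_major = any(.data$liver_extent == "major"),
      hospital_id = dplyr::first(.data$hospital_id),
      record = dplyr::first(.data$record),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      access = dplyr::case_when(
        .data$has_lap & .data$has_open ~ "converted",
        .data$has_lap ~ "laparoscopic",
        TRUE ~ "open"
      ),
      extent = dplyr::case_when(
        .data$organ_group != "liver" ~ "not_applicable",
        .data$has_major ~ "major",
        TRUE ~ "minor"
      )
    ) |>
    dplyr::select(-"has_lap", -"has_open", -"has_major") |>
    dplyr::rename(surgery_date = "date")
  n_candidates <- nrow(cand)

  ## colonic malignancy window
  diag <- diagnoses_long(admissions)
  malig <- diag[matches_malignancy(diag$code, codemap),
                c("patient_id", "date")]
  colonic <- cand$organ_group == "colonic"
  has_malig <- rep(FALSE, n_candidates)
  if (any(colonic) && nrow(malig) > 0) {
    hits <- cand[colonic, c("patient_id", "surgery_date")] |>
      dplyr::mutate(.i = which(colonic)) |>
      dplyr::inner_join(malig, by = "patient_id",
                        relationship = "many-to-many") |>
      dplyr::filter(abs(as.integer(.data$date - .data$surgery_date)) <= 30)
    has_malig[unique(hits$.i)] <- TRUE
  }
  drop_colonic <- colonic & !has_malig
  n_colonic_excl <- sum(drop_colonic)
  cand <- cand[!drop_colonic, , drop = FALSE]

  ## same-date ranking: keep the highest-ranked organ per (patient, date)
  cand$rank <- match(cand$organ_group, ORGAN_RANKING)
  cand <- cand |>
    dplyr::group_by(.data$patient_id, .data$surgery_date) |>
    dplyr::mutate(secondary = .data$rank > min(.data$rank)) |>
    dplyr::ungroup()
  n_secondary <- sum(cand$secondary)
  cand <- cand[!cand$secondary, , drop = FALSE]

  ## reoperation exclusion, per patient (single-candidate patients are
  ## trivially kept)
  multi <- cand$patient_id %in%
    cand$patient_id[duplicated(cand$patient_id)]
  keep1 <- cand[!multi, , drop = FALSE]
  n_reop <- 0L
  kept_multi <- NULL
  if (any(multi)) {
    parts <- split(cand[multi, , drop = FALSE], cand$patient_id[multi])
    res <- purrr::map(parts, exclude_reoperations)
    kept_multi <- dplyr::bind_rows(purrr::map(res, "kept"))
    n_reop <- sum(purrr::map_int(res, ~ nrow(.x$excluded)))
  }
  kept <- dplyr::bind_rows(keep1, kept_multi)

  cases <- tibble::tibble(
    case_id = paste0(kept$patient_id, "_", format(kept$surgery_date, "%Y%m%d")),
    patient_id = kept$patient_id,
    surgery_date = kept$surgery_date,
    hospital_id = kept$hospital_id,
    group = benchmark_group_of(kept$organ_group, kept$extent),
    access = kept$access,
    record = kept$record
  ) |>
    dplyr::arrange(.data$patient_id, .data$surgery_date)

  report <- new_extraction_report(
    n_candidates, n_colonic_excl, n_secondary + n_reop
  )
  stopifnot(report$n_final == nrow(cases))
  list(cases = cases, report = report)
}

empty_cohort <- function() {
  tibble::tibble(
    case_id = character(), patient_id = character(),
    surgery_date = as.Date(character()), hospital_id = character(),
    group = character(), access = character(), record = integer()
  )
}

new_extraction_report <- function(n_candidates, n_colonic, n_reop_secondary) {
  structure(
    list(
      n_candidate_resections = as.integer(n_candidates),
      n_colonic_excluded_no_malignancy = as.integer(n_colonic),
      n_excluded_reoperation_or_secondary = as.integer(n_reop_secondary),
      n_final = as.integer(n_candidates - n_colonic - n_reop_secondary)
    ),
    class = "extraction_report"
  )
}

#' @export
print.extraction_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<extraction_report>\n",
      "  candidate resections:               %d\n",
      "  colonic without malignancy code:   -%d\n",
      "  reoperations / secondary same-date: -%d\n",
      "  analysed cohort:                    %d\n"
    ),
    x$n_candidate_resections, x$n_colonic_excluded_no_malignancy,
    x$n_excluded_reoperation_or_secondary, x$n_final
  ))
  invisible(x)
}
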