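#' Admission registries
#'
#' An admission registry is a tibble with one row per hospital stay:
#' `patient_id`, `hospital_id`, `admission_date`, `discharge_date` (ISO
#' calendar dates; stays are counted in nights, never hours), and two packed
#' fields `procedures` and `diagnoses` holding semicolon-joined `code@date`
#' tokens (empty for non-surgical admissions). The packed representation is
#' used both on disk and in memory so national-scale registries (tens of
#' thousands of rows) stay flat and vectorisable; [procedures_long()] and
#' [diagnoses_long()] unpack to tidy long form.
#'
#' @name admission-registry
NULL

REGISTRY_COLUMNS <- c(
  "patient_id", "hospital_id", "admission_date", "discharge_date",
  "procedures", "diagnoses"
)

#' Read an admission registry file
#'
#' Reads a UTF-8 comma-delimited registry (header
#' `patient_id,hospital_id,admission_date,discharge_date,procedures,diagnoses`;
#' lines starting with `#` are treated as comments) and validates every row
#' against the record invariants: parseable ISO dates, discharge on or after
#' admission, non-empty patient and hospital identifiers, every procedure
#' dated within its stay, and well-formed `code@date` tokens.
#'
#' @param path path to the registry file.
#' @param strict if `TRUE`, any invalid row aborts; otherwise invalid rows
#'   are dropped and reported.
#' @return a list with elements `records` (the validated registry tibble)
#'   and `report` (a `validation_report`: `n_records`, `n_rejected`,
#'   `rejections` tibble with line numbers and reasons).
#' @export
#' @examples
#' reg <- generate_registry(default_config(cases_per_group = 5, seed = 1))
#' path <- tempfile(fileext = ".csv")
#' write_admissions(reg$admissions, path)
#' rt <- read_admissions(path)
#' rt$report
read_admissions <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("registry file not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", na = character(), progress = FALSE
  )
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "registry is missing required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- raw[REGISTRY_COLUMNS]
  validate_admissions(raw, strict = strict)
}

#' Write an admission registry file
#'
#' Inverse of [read_admissions()]: writes the registry as UTF-8 CSV with ISO
#' dates. `read_admissions(write_admissions(x, p))` returns `x` unchanged.
#'
#' @param records registry tibble (see [admission-registry]).
#' @param path output file path.
#' @param seed optional integer recorded as a `# seed=` comment header, so
#'   simulated registries carry their provenance.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(records, path, seed = NULL) {
  records <- as_registry(records)
  out <- records
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$discharge_date <- format(out$discharge_date, "%Y-%m-%d")
  lines <- c(
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
    paste(REGISTRY_COLUMNS, collapse = ","),
    if (nrow(out) > 0) {
      do.call(paste, c(unname(as.list(out)), sep = ","))
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## Coerce a data frame to the registry column set with Date columns.
as_registry <- function(x) {
  stopifnot(all(REGISTRY_COLUMNS %in% names(x)))
  x <- tibble::as_tibble(x)[REGISTRY_COLUMNS]
  x$admission_date <- as.Date(x$admission_date)
  x$discharge_date <- as.Date(x$discharge_date)
  x$procedures <- as.character(x$procedures)
  x$diagnoses <- as.character(x$diagnoses)
  x$procedures[is.na(x$procedures)] <- ""
  x$diagnoses[is.na(x$diagnoses)] <- ""
  x
}

## Validate a character-typed registry tibble row-wise; returns records +
## validation_report. Total: every row is either accepted or rejected with
## a reason.
validate_admissions <- function(raw, strict = FALSE) {
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  note <- function(bad, why) {
    fresh <- bad & is.na(reason)
    reason[fresh] <<- why
  }

  adm <- suppressWarnings(as.Date(raw$admission_date, format = "%Y-%m-%d"))
  dis <- suppressWarnings(as.Date(raw$discharge_date, format = "%Y-%m-%d"))
  note(is.na(raw$patient_id) | raw$patient_id == "", "empty patient_id")
  note(is.na(raw$hospital_id) | raw$hospital_id == "", "empty hospital_id")
  note(is.na(adm), "unparseable admission_date")
  note(is.na(dis), "unparseable discharge_date")
  note(!is.na(adm) & !is.na(dis) & dis < adm, "discharge before admission")

  ## token syntax + procedure-dates-within-stay, vectorised over the packed
  ## fields
  check_tokens <- function(field, within_stay) {
    txt <- raw[[field]]
    txt[is.na(txt)] <- ""
    has <- txt != ""
    toks <- strsplit(txt[has], ";", fixed = TRUE)
    row_of <- rep(which(has), lengths(toks))
    tok <- unlist(toks, use.names = FALSE)
    if (length(tok) == 0) return(invisible())
    parts <- strsplit(tok, "@", fixed = TRUE)
    ok_shape <- lengths(parts) == 2
    code <- vapply(parts, function(p) p[1], "", USE.NAMES = FALSE)
    dstr <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
    d <- suppressWarnings(as.Date(dstr, format = "%Y-%m-%d"))
    bad_rows <- unique(row_of[!ok_shape | code == "" | is.na(d)])
    if (length(bad_rows) > 0) {
      flag <- rep(FALSE, n); flag[bad_rows] <- TRUE
      note(flag, paste0("malformed ", field, " token"))
    }
    if (within_stay) {
      inside <- !is.na(d) & !is.na(adm[row_of]) & !is.na(dis[row_of]) &
        d >= adm[row_of] & d <= dis[row_of]
      out_rows <- unique(row_of[ok_shape & !is.na(d) & !inside])
      if (length(out_rows) > 0) {
        flag <- rep(FALSE, n); flag[out_rows] <- TRUE
        note(flag, "procedure date outside stay")
      }
    }
    invisible()
  }
  check_tokens("procedures", within_stay = TRUE)
  check_tokens("diagnoses", within_stay = FALSE)

  bad <- !is.na(reason)
  rejections <- tibble::tibble(line = which(bad), reason = reason[bad])
  if (strict && nrow(rejections) > 0) {
    abort(paste0(
      "invalid registry rows (strict mode): ",
      paste(sprintf("row %d: %s", head(rejections$line, 5),
                    head(rejections$reason, 5)), collapse = "; "),
      if (nrow(rejections) > 5) sprintf(" ... and %d more", nrow(rejections) - 5)
    ))
  }
  records <- as_registry(raw[!bad, , drop = FALSE])
  report <- structure(
    list(n_records = n, n_rejected = nrow(rejections), rejections = rejections),
    class = "validation_report"
  )
  list(records = records, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d record(s) read, %d rejected\n",
    x$n_records, x$n_rejected
  ))
  if (x$n_rejected > 0) print(x$rejections, n = 10)
  invisible(x)
}

#' Unpack procedures to long form
#'
#' @param records registry tibble.
#' @return tibble with one row per dated procedure code: `record` (row index
#'   into `records`), `patient_id`, `hospital_id`, `admission_date`,
#'   `discharge_date`, `code`, `date`.
#' @export
procedures_long <- function(records) {
  unpack_long(records, "procedures")
}

#' Unpack diagnoses to long form
#' @inheritParams procedures_long
#' @return tibble as in [procedures_long()].
#' @export
diagnoses_long <- function(records) {
  unpack_long(records, "diagnoses")
}

unpack_long <- function(records, field) {
  records <- as_registry(records)
  txt <- records[[field]]
  has <- !is.na(txt) & txt != ""
  toks <- strsplit(txt[has], ";", fixed = TRUE)
  row_of <- rep(which(has), lengths(toks))
  tok <- unlist(toks, use.names = FALSE)
  if (length(tok) == 0) {
    return(tibble::tibble(
      record = integer(), patient_id = character(), hospital_id = character(),
      admission_date = as.Date(character()), discharge_date = as.Date(character()),
      code = character(), date = as.Date(character())
    ))
  }
  at <- regexpr("@", tok, fixed = TRUE)
  tibble::tibble(
    record = row_of,
    patient_id = records$patient_id[row_of],
    hospital_id = records$hospital_id[row_of],
    admission_date = records$admission_date[row_of],
    discharge_date = records$discharge_date[row_of],
    code = substr(tok, 1, at - 1),
    date = as.Date(substr(tok, at + 1, nchar(tok)))
  )
}

## Pack a long (code, date) pair vector into the on-disk token form.
pack_tokens <- function(code, date) {
  if (length(code) == 0) return("")
  paste(sprintf("%s@%s", code, format(date, "%Y-%m-%d")), collapse = ";")
}
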