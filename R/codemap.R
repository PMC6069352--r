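#' Load a procedure/diagnosis code map
#'
#' A code map drives cohort extraction: it maps resection procedure codes to
#' an organ group (`oesophageal`, `gastric`, `liver`, `pancreatoduodenal`,
#' `distal_pancreatic`, `colonic`, `rectal`), an access flag (`open` or
#' `laparoscopic` -- laparoscopic resections carry designated codes), and,
#' for liver codes only, a resection extent (`major` for three or more
#' consecutive segments, else `minor`). It also lists diagnosis-code
#' prefixes that identify colonic malignancy.
#'
#' The config is YAML with a `procedures` list of entries
#' `{code, organ, access, extent}` (extent only for liver) and a
#' `colonic_malignancy_patterns` list of prefixes. The bundled default map
#' (used when `path` is `NULL`) uses NCSP-style code stems; it is
#' illustrative -- national registries do not publish their extraction code
#' lists -- and should be replaced with a site-specific map for real data.
#'
#' @param path path to a YAML code-map config, or `NULL` for the bundled
#'   default map.
#' @return a `codemap`: list with `procedures` (tibble `code`,
#'   `organ_group`, `access`, `liver_extent`) and
#'   `colonic_malignancy_patterns` (character).
#' @export
#' @examples
#' cm <- load_codemap()
#' cm$procedures
load_codemap <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_codemap.yaml", package = "alosbench")
  }
  if (!file.exists(path)) abort(paste0("code map config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$procedures) || length(cfg$procedures) == 0) {
    abort("code map config has no 'procedures' section")
  }
  entries <- purrr::map(cfg$procedures, function(e) {
    tibble::tibble(
      code = as.character(e$code %||% ""),
      organ_group = as.character(e$organ %||% ""),
      access = as.character(e$access %||% ""),
      liver_extent = as.character(e$extent %||% "not_applicable")
    )
  })
  procedures <- dplyr::bind_rows(entries)
  patterns <- as.character(unlist(cfg$colonic_malignancy_patterns))
  new_codemap(procedures, patterns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ORGAN_GROUPS <- c(
  "oesophageal", "gastric", "liver", "pancreatoduodenal",
  "distal_pancreatic", "colonic", "rectal"
)

## Construct + validate a codemap.
new_codemap <- function(procedures, colonic_malignancy_patterns) {
  p <- tibble::as_tibble(procedures)
  stopifnot(all(c("code", "organ_group", "access", "liver_extent") %in% names(p)))
  if (any(p$code == "")) abort("code map entry with empty code")
  dup <- unique(p$code[duplicated(p$code)])
  if (length(dup) > 0) {
    abort(paste0("duplicate procedure code(s) in code map: ",
                 paste(dup, collapse = ", ")))
  }
  bad_org <- setdiff(unique(p$organ_group), ORGAN_GROUPS)
  if (length(bad_org) > 0) {
    abort(paste0("unknown organ group(s): ", paste(bad_org, collapse = ", ")))
  }
  bad_acc <- setdiff(unique(p$access), c("open", "laparoscopic"))
  if (length(bad_acc) > 0) {
    abort(paste0("unknown access flag(s): ", paste(bad_acc, collapse = ", ")))
  }
  liver_no_extent <- p$organ_group == "liver" &
    !p$liver_extent %in% c("major", "minor")
  if (any(liver_no_extent)) {
    abort(paste0("liver code(s) without major/minor extent: ",
                 paste(p$code[liver_no_extent], collapse = ", ")))
  }
  nonliver_extent <- p$organ_group != "liver" & p$liver_extent != "not_applicable"
  if (any(nonliver_extent)) {
    abort(paste0("non-liver code(s) carry a liver extent: ",
                 paste(p$code[nonliver_extent], collapse = ", ")))
  }
  if (length(colonic_malignancy_patterns) == 0) {
    abort("code map has no colonic malignancy diagnosis patterns")
  }
  structure(
    list(procedures = p,
         colonic_malignancy_patterns = as.character(colonic_malignancy_patterns)),
    class = "codemap"
  )
}

#' @export
print.codemap <- function(x, ...) {
  cat(sprintf(
    "<codemap> %d procedure code(s) over %d organ group(s); colonic malignancy prefixes: %s\n",
    nrow(x$procedures), dplyr::n_distinct(x$procedures$organ_group),
    paste(x$colonic_malignancy_patterns, collapse = ", ")
  ))
  invisible(x)
}

#' Liver resection extent for a procedure code
#'
#' Returns `"major"` (three or more consecutive segments) or `"minor"` for a
#' liver resection code; errors on codes not mapped to the liver group.
#'
#' @param code a single procedure code.
#' @param codemap a [load_codemap()] object.
#' @return `"major"` or `"minor"`.
#' @export
split_liver_extent <- function(code, codemap) {
  stopifnot(inherits(codemap, "codemap"), length(code) == 1)
  row <- codemap$procedures[codemap$procedures$code == code, ]
  if (nrow(row) == 0) abort(paste0("unknown procedure code: ", code))
  if (row$organ_group != "liver") {
    abort(paste0("not a liver resection code: ", code,
                 " (", row$organ_group, ")"))
  }
  row$liver_extent
}

## Does a diagnosis code match any colonic malignancy prefix?
matches_malignancy <- function(codes, codemap) {
  if (length(codes) == 0) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in codemap$colonic_malignancy_patterns) {
    hit <- hit | startsWith(codes, p)
  }
  hit
}
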