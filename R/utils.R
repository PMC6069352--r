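#' Round half-up to a fixed number of decimals
#'
#' Commercial ("half-up") rounding, used for all percentages so that printed
#' rates follow the one-decimal convention of clinical benchmark tables
#' (base `round()` rounds half to even). A tiny epsilon guards against
#' binary representation of exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Largest-remainder apportionment of n into parts
#'
#' Splits an integer total over probability weights so the parts sum exactly
#' to `n`, deterministically. Used to allocate case counts across access
#' classes in the simulator.
#'
#' @param n integer total.
#' @param w non-negative weights (need not sum to 1).
#' @return integer vector, same length as `w`, summing to `n`.
#' @keywords internal
apportion <- function(n, w) {
  stopifnot(n >= 0, all(w >= 0), sum(w) > 0)
  q <- n * w / sum(w)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    take <- order(q - k, decreasing = TRUE)[seq_len(rem)]
    k[take] <- k[take] + 1
  }
  as.integer(k)
}

## The eight benchmark groups, in fixed reporting order.
BENCHMARK_GROUPS <- c(
  "oesophageal", "whipple", "rectal", "gastric",
  "distal_pancreatic", "colonic", "major_liver", "minor_liver"
)

## Organ-site ranking used when two resections share a date: the
## higher-ranked (earlier) site is kept, the other treated as secondary.
ORGAN_RANKING <- c(
  "oesophageal", "pancreatoduodenal", "rectal", "gastric",
  "distal_pancreatic", "colonic", "liver"
)

ACCESS_LEVELS <- c("laparoscopic", "open", "converted")

## organ group + liver extent -> benchmark group
benchmark_group_of <- function(organ, extent) {
  dplyr::case_when(
    organ == "pancreatoduodenal" ~ "whipple",
    organ == "liver" & extent == "major" ~ "major_liver",
    organ == "liver" ~ "minor_liver",
    TRUE ~ organ
  )
}
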