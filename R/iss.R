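#' Six classic ISS body regions
#' @return Character vector of region labels.
#' @export
iss_body_regions <- function() {
  c("head", "face", "thorax", "abdomen", "extremities", "external")
}

#' Compute the Injury Severity Score from AIS-coded injuries
#'
#' The ISS is the sum of squares of the highest Abbreviated Injury Scale
#' (AIS) severity in each of the three most severely injured of the six
#' classic body regions (head, face, thorax, abdomen, extremities,
#' external). An empty injury list scores 0. By the standard convention any
#' AIS severity-6 (currently untreatable) injury sets the ISS to the
#' maximum of 75; all scores are bounded by 75.
#'
#' @param injuries Data frame (or tibble) with columns `region` (one of
#'   [iss_body_regions()]) and `severity` (integer 1-6); extra columns such
#'   as `open_fracture` are ignored. `NULL` or zero rows score 0.
#' @return Integer ISS in `[0, 75]`.
#' @examples
#' compute_iss(data.frame(region = c("head", "thorax", "extremities"),
#'                        severity = c(4, 3, 2)))          # 16 + 9 + 4 = 29
#' compute_iss(data.frame(region = "thorax", severity = c(3, 5)))  # 25
#' @export
compute_iss <- function(injuries) {
  if (is.null(injuries) || nrow(injuries) == 0) return(0L)
  sev <- injuries$severity
  reg <- injuries$region
  if (anyNA(sev) || any(sev < 1) || any(sev > 6) || any(sev != floor(sev)))
    abort("AIS severity must be an integer in 1..6",
          class = "triagecc_config_error")
  bad <- setdiff(unique(reg), iss_body_regions())
  if (length(bad))
    abort(sprintf("unknown AIS body region(s): %s", paste(bad, collapse = ", ")),
          class = "triagecc_config_error")
  if (any(sev == 6)) return(75L)
  maxima <- tapply(sev, reg, max)
  top <- sort(as.integer(maxima), decreasing = TRUE)
  as.integer(min(75L, sum(head(top, 3)^2)))
}

#' Append the ISS to a record table
#'
#' @param records Tibble of incident records with an `injuries` list-column
#'   (each element a data frame of `region`, `severity`, `open_fracture`).
#' @return `records` with an integer `iss` column appended.
#' @export
add_iss <- function(records) {
  dplyr::mutate(records, iss = purrr::map_int(.data$injuries, compute_iss))
}
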