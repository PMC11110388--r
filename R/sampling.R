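#' Draw a case-cohort analysis sample
#'
#' The analysis set is the union of (a) a sub-cohort of `subcohort_size`
#' records sampled uniformly at random irrespective of reference-standard
#' status and (b) every reference-standard-positive record ("case").
#' Positives that happen to fall in the sub-cohort are retained once with
#' both provenance flags set.
#'
#' @param cohort Tibble of incident records.
#' @param subcohort_size Number of records in the random sub-cohort; must
#'   not exceed the cohort size.
#' @param truth Name of the logical status column used to identify cases
#'   (default `"true_status"`), or a logical vector of length `nrow(cohort)`.
#' @param seed Seed for the sub-cohort draw.
#' @return Tibble of analysis-set records (no duplicates) with logical
#'   provenance columns `in_subcohort` and `is_case`.
#' @examples
#' cohort <- generate_parent_cohort(population_config(n_incidents = 1000, seed = 7))
#' s <- draw_case_cohort_sample(cohort, subcohort_size = 200, seed = 7)
#' sum(s$is_case) == sum(cohort$true_status)
#' @export
draw_case_cohort_sample <- function(cohort, subcohort_size,
                                    truth = "true_status", seed = 1L) {
  n <- nrow(cohort)
  if (subcohort_size > n)
    abort(sprintf("subcohort_size (%d) exceeds cohort size (%d)",
                  subcohort_size, n), class = "triagecc_config_error")
  status <- if (is.character(truth)) cohort[[truth]] else truth
  if (length(status) != n || anyNA(status))
    abort("`truth` must resolve to a complete logical status per record",
          class = "triagecc_config_error")
  sub_idx <- withr::with_seed(derive_seed(seed, "subcohort"),
                              sample.int(n, subcohort_size))
  in_sub <- seq_len(n) %in% sub_idx
  keep <- in_sub | status
  out <- cohort[keep, ]
  out$in_subcohort <- in_sub[keep]
  out$is_case <- status[keep]
  out
}

#' Deterministically link registry cases to ambulance records
#'
#' Exact matching on the shared report-form identifier only. Cases whose
#' key is missing, or whose key occurs more than once in either source
#' (ambiguous), are reported unmatched; no probabilistic fallback is
#' attempted.
#'
#' @param cases Tibble of registry-identified cases carrying
#'   `report_form_id`.
#' @param ambulance_records Tibble of ambulance records carrying
#'   `report_form_id`.
#' @return List with `matched` (the subset of `cases` whose key resolves to
#'   exactly one ambulance record, with `ambulance_record_id` appended) and
#'   `report` (one-row tibble of match accounting, including `match_rate`).
#' @export
link_records <- function(cases, ambulance_records) {
  for (d in list(cases, ambulance_records))
    if (!"report_form_id" %in% names(d))
      abort("both sources must carry `report_form_id`",
            class = "triagecc_config_error")
  case_key <- cases$report_form_id
  amb_key <- ambulance_records$report_form_id
  dup_case <- case_key[!is.na(case_key)][duplicated(case_key[!is.na(case_key)])]
  amb_tab <- table(amb_key[!is.na(amb_key)])
  dup_amb <- names(amb_tab)[amb_tab > 1]

  missing_key <- is.na(case_key)
  ambiguous <- !missing_key & (case_key %in% dup_case | case_key %in% dup_amb)
  amb_unique <- !is.na(amb_key) & !(amb_key %in% dup_amb)
  pos <- match(case_key, ifelse(amb_unique, amb_key, NA_character_))
  matched_flag <- !missing_key & !ambiguous & !is.na(pos)

  matched <- cases[matched_flag, ]
  matched$ambulance_record_id <- ambulance_records$record_id[pos[matched_flag]]
  n <- nrow(cases)
  report <- tibble::tibble(
    n_cases = n,
    matched = sum(matched_flag),
    unmatched_missing_key = sum(missing_key),
    unmatched_ambiguous = sum(ambiguous),
    unmatched_no_match = n - sum(matched_flag) - sum(missing_key) - sum(ambiguous),
    match_rate = if (n > 0) sum(matched_flag) / n else NA_real_)
  list(matched = matched, report = report)
}
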