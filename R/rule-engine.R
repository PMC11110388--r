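#' Derive categorical injury-pattern labels from a record's coded injuries
#'
#' Anatomy-step criteria test set membership over a small derived
#' vocabulary: `penetrating_torso` (penetrating mode with a thorax or
#' abdomen injury), `penetrating_head_neck` (penetrating mode with a head
#' or face injury), `open_fracture` (any open fracture), and
#' `severe_extremity_injury` (extremity injury of AIS severity 3 or more).
#'
#' @param injuries Data frame of coded injuries (`region`, `severity`,
#'   `open_fracture`).
#' @param mode `"blunt"` or `"penetrating"`.
#' @return Character vector of pattern labels (possibly empty).
#' @export
derive_injury_patterns <- function(injuries, mode) {
  if (is.null(injuries) || nrow(injuries) == 0) return(character())
  out <- character()
  if (identical(mode, "penetrating")) {
    if (any(injuries$region %in% c("thorax", "abdomen")))
      out <- c(out, "penetrating_torso")
    if (any(injuries$region %in% c("head", "face")))
      out <- c(out, "penetrating_head_neck")
  }
  open <- if ("open_fracture" %in% names(injuries)) injuries$open_fracture
          else rep(FALSE, nrow(injuries))
  if (any(open)) out <- c(out, "open_fracture")
  if (any(injuries$region == "extremities" & injuries$severity >= 3))
    out <- c(out, "severe_extremity_injury")
  out
}

derive_special_circumstances <- function(record_row) {
  out <- character()
  if (isTRUE(record_row$hems_response)) out <- c(out, "hems_attendance")
  if (record_row$age_years >= 65) out <- c(out, "older_adult")
  if (record_row$age_years < 16) out <- c(out, "child")
  out
}

comparator_fun <- function(cmp) {
  switch(cmp, "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`, "==" = `==`,
         abort(sprintf("unknown comparator '%s'", cmp)))
}

missing_abort <- function(variable, record_id = NULL) {
  abort(sprintf("required variable '%s' is missing%s; records must pass the complete-case filter",
                variable,
                if (is.null(record_id)) "" else sprintf(" for record %s", record_id)),
        class = "triagecc_missing_data")
}

#' Evaluate a single criterion against one incident record
#'
#' Non-sustained physiological criteria compare the *first recorded* value
#' of the vital-sign series. Sustained criteria are satisfied if and only
#' if some run of two or more consecutive measurements (in recording order)
#' all meet the threshold; a single-measurement series can never satisfy a
#' sustained criterion. Categorical criteria test set membership of the
#' record's mechanism class, derived injury patterns, or special
#' circumstances. A missing required variable raises an explicit
#' missing-data error rather than silently returning `FALSE`.
#'
#' @param record One-row tibble of an incident record.
#' @param criterion A [triage_criterion()].
#' @return List with `result` (logical) and `evidence`: a tibble of the
#'   measurement index/value (or category) that was used, with the
#'   satisfying measurements marked.
#' @examples
#' rec <- tibble::tibble(
#'   record_id = "r1", age_years = 40, mechanism = "fall_lt_1m",
#'   mode = "blunt", hems_response = FALSE,
#'   vitals = list(data.frame(minute = c(0, 10), sbp = c(85, 110),
#'                            rr = c(18, 20), spo2 = c(97, 98), gcs = c(15, 15))),
#'   injuries = list(data.frame(region = "head", severity = 2,
#'                              open_fracture = FALSE)))
#' evaluate_criterion(rec, triage_criterion("sbp", "<", 90))$result  # TRUE
#' @export
evaluate_criterion <- function(record, criterion) {
  stopifnot(inherits(criterion, "triage_criterion"), nrow(record) == 1)
  vars <- criterion_variables()
  v <- criterion$variable
  rid <- record$record_id %||% NULL

  if (v %in% vars$physiology) {
    series <- record$vitals[[1]]
    if (is.null(series) || nrow(series) == 0 || !v %in% names(series))
      missing_abort(v, rid)
    x <- series[[v]]
    cmp <- comparator_fun(criterion$comparator)
    if (!criterion$sustained) {
      if (is.na(x[1])) missing_abort(v, rid)
      res <- cmp(x[1], criterion$threshold)
      ev <- tibble::tibble(measurement = 1L, value = x[1], satisfied = res)
    } else {
      hit <- cmp(x, criterion$threshold)
      hit[is.na(hit)] <- FALSE
      runs <- hit[-length(hit)] & hit[-1]
      res <- length(x) >= 2 && any(runs)
      ev <- tibble::tibble(measurement = seq_along(x), value = x, satisfied = hit)
    }
    return(list(result = res, evidence = ev))
  }

  if (v == "age") {
    if (is.na(record$age_years)) missing_abort(v, rid)
    cmp <- comparator_fun(criterion$comparator)
    res <- cmp(record$age_years, criterion$threshold)
    return(list(result = res,
                evidence = tibble::tibble(measurement = NA_integer_,
                                          value = record$age_years, satisfied = res)))
  }

  value <- switch(v,
    mechanism = record$mechanism,
    injury_pattern = derive_injury_patterns(record$injuries[[1]], record$mode),
    special_circumstance = derive_special_circumstances(record))
  if (v == "mechanism" && (is.null(value) || is.na(value))) missing_abort(v, rid)
  res <- any(value %in% criterion$threshold)
  list(result = res,
       evidence = tibble::tibble(measurement = NA_integer_,
                                 value = paste(value[value %in% criterion$threshold],
                                               collapse = ";"),
                                 satisfied = res))
}

#' Evaluate a triage tool cumulatively against one record, with evidence
#'
#' Each step result is the OR of its criteria; the cumulative result at
#' depth *k* is the OR of steps 1..*k* (so it is monotone non-decreasing in
#' depth); `final_mandatory` is the OR over mandatory steps only and
#' `final_all_steps` over every step. Every criterion's verdict is returned
#' with the measurement evidence that produced it.
#'
#' @param record One-row tibble of an incident record.
#' @param tool A [triage_tool()].
#' @return Object of class `triage_evaluation`: list with `per_criterion`
#'   (tibble), `per_step` (named logical), `cumulative` (named logical by
#'   depth), `final_mandatory`, `final_all_steps`.
#' @export
evaluate_tool_cumulative <- function(record, tool) {
  stopifnot(inherits(tool, "triage_tool"), nrow(record) == 1)
  per_crit <- list(); step_res <- logical(length(tool$steps))
  for (i in seq_along(tool$steps)) {
    s <- tool$steps[[i]]
    crit_res <- logical(length(s$criteria))
    for (j in seq_along(s$criteria)) {
      cr <- s$criteria[[j]]
      ev <- evaluate_criterion(record, cr)
      crit_res[j] <- ev$result
      per_crit[[length(per_crit) + 1]] <- tibble::tibble(
        step = s$index, criterion = j, variable = cr$variable,
        comparator = cr$comparator,
        threshold = paste(cr$threshold, collapse = ","),
        description = cr$description, result = ev$result,
        evidence = list(ev$evidence))
    }
    step_res[i] <- any(crit_res)
  }
  idx <- vapply(tool$steps, `[[`, 1L, "index")
  depths <- seq_len(max(idx))
  cumulative <- vapply(depths, function(k) any(step_res[idx <= k]), TRUE)
  names(cumulative) <- paste0("depth_", depths)
  mand <- vapply(tool$steps, `[[`, TRUE, "mandatory")
  structure(list(
    service = tool$service_label,
    per_criterion = dplyr::bind_rows(per_crit),
    per_step = setNames(step_res, paste0("step_", idx)),
    cumulative = cumulative,
    final_mandatory = any(step_res[mand]),
    final_all_steps = any(step_res)
  ), class = "triage_evaluation")
}

#' @export
print.triage_evaluation <- function(x, ...) {
  cat(sprintf("<triage_evaluation> tool %s\n", x$service))
  cat("  steps:     ", paste(sprintf("%s=%s", names(x$per_step), x$per_step),
                             collapse = " "), "\n")
  cat("  cumulative:", paste(sprintf("%s=%s", names(x$cumulative), x$cumulative),
                             collapse = " "), "\n")
  cat(sprintf("  mandatory-only: %s   all steps: %s\n",
              x$final_mandatory, x$final_all_steps))
  invisible(x)
}

# n x K matrix of one vital-sign signal across records, NA-padded
signal_matrix <- function(vitals, signal) {
  k <- vapply(vitals, function(v) if (is.null(v)) 0L else nrow(v), integer(1))
  K <- max(k, 1L)
  rows <- lapply(vitals, function(v) {
    x <- if (is.null(v) || nrow(v) == 0) numeric() else as.numeric(v[[signal]])
    c(x, rep(NA_real_, K - length(x)))
  })
  matrix(unlist(rows), ncol = K, byrow = TRUE)
}

# vectorised criterion evaluation over a record table; returns the logical
# result vector plus a per-record missing-data flag
evaluate_criterion_vec <- function(records, criterion, sig_mats, patterns, specials) {
  vars <- criterion_variables()
  v <- criterion$variable
  if (v %in% vars$physiology) {
    M <- sig_mats[[v]]
    cmp <- comparator_fun(criterion$comparator)
    if (!criterion$sustained) {
      first <- M[, 1]
      res <- cmp(first, criterion$threshold)
      miss <- is.na(first)
      res[miss] <- FALSE
    } else {
      hit <- cmp(M, criterion$threshold)
      hit[is.na(hit)] <- FALSE
      res <- rep(FALSE, nrow(M))
      if (ncol(M) >= 2)
        for (j in seq_len(ncol(M) - 1)) res <- res | (hit[, j] & hit[, j + 1])
      miss <- rowSums(!is.na(M)) == 0   # empty series only
    }
    return(list(result = res, missing = miss, variable = v))
  }
  if (v == "age") {
    miss <- is.na(records$age_years)
    res <- comparator_fun(criterion$comparator)(records$age_years, criterion$threshold)
    res[miss] <- FALSE
    return(list(result = res, missing = miss, variable = v))
  }
  if (v == "mechanism") {
    miss <- is.na(records$mechanism)
    return(list(result = records$mechanism %in% criterion$threshold & !miss,
                missing = miss, variable = v))
  }
  pool <- if (v == "injury_pattern") patterns else specials
  list(result = vapply(pool, function(p) any(p %in% criterion$threshold), logical(1)),
       missing = rep(FALSE, nrow(records)), variable = v)
}

#' Evaluate a triage tool against a table of records
#'
#' Vectorised engine producing, per record, each step result, the
#' cumulative result at every step depth, the mandatory-steps-only result
#' and the all-steps result. Semantics are identical to
#' [evaluate_tool_cumulative()] applied row-wise.
#'
#' @param records Tibble of incident records (complete cases).
#' @param tool A [triage_tool()].
#' @param mode `"complete_case"` (default): a missing required variable
#'   anywhere raises an error. `"criterion_skip"`: a criterion that cannot
#'   be evaluated is treated as unsatisfied and the record is flagged in
#'   the `skipped` column.
#' @return Tibble with `record_id`, `step_<i>` logicals, `cumulative_<k>`
#'   logicals, `final_mandatory`, `final_all_steps` and (in
#'   `criterion_skip` mode) `skipped`.
#' @export
evaluate_tool <- function(records, tool,
                          mode = c("complete_case", "criterion_skip")) {
  stopifnot(inherits(tool, "triage_tool"))
  mode <- match.arg(mode)
  n <- nrow(records)
  sig_mats <- lapply(setNames(nm = criterion_variables()$physiology),
                     function(s) signal_matrix(records$vitals, s))
  patterns <- purrr::map2(records$injuries, records$mode, derive_injury_patterns)
  specials <- purrr::map(seq_len(n), function(i) {
    out <- character()
    if (isTRUE(records$hems_response[i])) out <- c(out, "hems_attendance")
    if (records$age_years[i] >= 65) out <- c(out, "older_adult")
    if (records$age_years[i] < 16) out <- c(out, "child")
    out
  })
  skipped <- rep(FALSE, n)
  idx <- vapply(tool$steps, `[[`, 1L, "index")
  step_cols <- list()
  for (i in seq_along(tool$steps)) {
    s <- tool$steps[[i]]
    res <- rep(FALSE, n)
    for (cr in s$criteria) {
      r <- evaluate_criterion_vec(records, cr, sig_mats, patterns, specials)
      if (any(r$missing)) {
        if (mode == "complete_case") missing_abort(r$variable)
        skipped <- skipped | r$missing
      }
      res <- res | r$result
    }
    step_cols[[paste0("step_", s$index)]] <- res
  }
  out <- tibble::tibble(record_id = records$record_id)
  out <- dplyr::bind_cols(out, tibble::as_tibble(step_cols))
  step_mat <- do.call(cbind, step_cols)
  for (k in seq_len(max(idx)))
    out[[paste0("cumulative_", k)]] <-
      rowSums(step_mat[, idx <= k, drop = FALSE]) > 0
  mand <- vapply(tool$steps, `[[`, TRUE, "mandatory")
  out$final_mandatory <- rowSums(step_mat[, mand, drop = FALSE]) > 0
  out$final_all_steps <- rowSums(step_mat) > 0
  if (mode == "criterion_skip") out$skipped <- skipped
  out
}
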