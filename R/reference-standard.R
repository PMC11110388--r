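#' Configure the consensus (MATTS-style) reference standard
#'
#' The primary reference standard classifies an injured patient as
#' benefiting from expedited major trauma centre care when *any* of four
#' domains holds: (1) need for critical interventions; (2) a significant
#' individual anatomical injury; (3) a burden of multiple injuries; (4)
#' patient characteristics indicating capacity to benefit from specialist
#' care. The operational clinical lists behind each domain are defined by
#' an external consensus process, so every domain is configurable here; the
#' defaults are a documented, conventional placeholder set, not the
#' authoritative clinical definition.
#'
#' @param urgent_interventions Character set of intervention labels counted
#'   as critical interventions (domain 1).
#' @param significant_injury_rules Data frame of predicates over single
#'   injuries (domain 2), columns: `region` (a body region or `"any"`),
#'   `min_severity` (AIS 1-6), `open_fracture_only` (logical; rule fires
#'   only for open fractures).
#' @param multiple_injury Domain 3 predicate: list with `min_regions` and
#'   `min_severity` — at least `min_regions` distinct body regions each with
#'   maximum AIS severity at or above `min_severity`.
#' @param capacity_to_benefit Domain 4 predicate: list with `min_age`
#'   (years), `min_severity`, and `require_injury` (if `TRUE`, never positive
#'   without at least one coded injury — the default reading).
#' @param iss_threshold ISS cut-off for the secondary anatomical reference
#'   standard (default 16).
#' @return Object of class `reference_standard_config`.
#' @export
reference_standard_config <- function(
    urgent_interventions = c("intubation", "thoracostomy", "blood_transfusion",
                             "emergency_surgery", "interventional_radiology"),
    significant_injury_rules = tibble::tribble(
      ~region, ~min_severity, ~open_fracture_only,
      "any",    4L,            FALSE,
      "head",   3L,            FALSE,
      "any",    2L,            TRUE),
    multiple_injury = list(min_regions = 2L, min_severity = 3L),
    capacity_to_benefit = list(min_age = 65, min_severity = 3L,
                               require_injury = TRUE),
    iss_threshold = 16L) {
  if (length(urgent_interventions) == 0)
    config_abort("urgent_interventions", "must name at least one intervention")
  need <- c("region", "min_severity", "open_fracture_only")
  if (!all(need %in% names(significant_injury_rules)) ||
      nrow(significant_injury_rules) == 0)
    config_abort("significant_injury_rules",
                 "must be a non-empty table with region/min_severity/open_fracture_only")
  bad <- setdiff(significant_injury_rules$region, c("any", iss_body_regions()))
  if (length(bad))
    config_abort("significant_injury_rules$region",
                 sprintf("contains unknown region(s): %s", paste(bad, collapse = ", ")))
  for (f in c("min_regions", "min_severity"))
    if (is.null(multiple_injury[[f]])) config_abort(paste0("multiple_injury$", f), "is missing")
  for (f in c("min_age", "min_severity", "require_injury"))
    if (is.null(capacity_to_benefit[[f]])) config_abort(paste0("capacity_to_benefit$", f), "is missing")
  if (!is.numeric(iss_threshold) || iss_threshold < 0)
    config_abort("iss_threshold", "must be a non-negative integer")
  structure(list(urgent_interventions = urgent_interventions,
                 significant_injury_rules = tibble::as_tibble(significant_injury_rules),
                 multiple_injury = multiple_injury,
                 capacity_to_benefit = capacity_to_benefit,
                 iss_threshold = as.integer(iss_threshold)),
            class = "reference_standard_config")
}

# per-record domain flags, vectorised over an unnested injury table;
# open-fracture rules can be excluded to support the "without open
# fractures" secondary standard
matts_domain_flags <- function(records, config, include_open_fracture_rules = TRUE) {
  n <- nrow(records)
  inj <- records$injuries
  rules <- config$significant_injury_rules
  if (!include_open_fracture_rules) rules <- rules[!rules$open_fracture_only, ]
  mi <- config$multiple_injury
  cb <- config$capacity_to_benefit

  critical <- purrr::map_lgl(records$interventions,
                             ~ length(intersect(.x, config$urgent_interventions)) > 0)

  ninj <- vapply(inj, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  sig <- logical(n); multi <- logical(n); any_cb_sev <- logical(n)
  if (any(ninj > 0)) {
    long <- dplyr::bind_rows(inj[ninj > 0])
    id <- rep(which(ninj > 0), ninj[ninj > 0])
    open <- if ("open_fracture" %in% names(long)) long$open_fracture else rep(FALSE, nrow(long))
    sig_long <- rep(FALSE, nrow(long))
    for (j in seq_len(nrow(rules))) {
      sig_long <- sig_long |
        (long$severity >= rules$min_severity[j] &
           (rules$region[j] == "any" | long$region == rules$region[j]) &
           (!rules$open_fracture_only[j] | open))
    }
    sig[sort(unique(id))] <- rowsum(as.integer(sig_long), id)[, 1] > 0
    # distinct regions whose maximum severity reaches the multiple-injury bar
    key <- paste(id, long$region)
    sev_max <- tapply(long$severity, key, max)
    reg_id <- as.integer(vapply(strsplit(names(sev_max), " "), `[`, "", 1))
    hits <- rowsum(as.integer(sev_max >= mi$min_severity), reg_id)
    multi[as.integer(rownames(hits))] <- hits[, 1] >= mi$min_regions
    any_cb_sev[sort(unique(id))] <- rowsum(as.integer(long$severity >= cb$min_severity), id)[, 1] > 0
  }
  capacity <- records$age_years >= cb$min_age &
    if (isTRUE(cb$require_injury)) any_cb_sev else (any_cb_sev | TRUE)
  tibble::tibble(critical_interventions = critical, significant_injury = sig,
                 multiple_injury = multi, capacity_to_benefit = capacity)
}

#' Classify a single record against the consensus reference standard
#'
#' @param record One-row tibble of an incident record (list-columns
#'   `injuries`, `interventions`, numeric `age_years`).
#' @param config A [reference_standard_config()].
#' @return List with `positive` (logical) and `domains` (character vector of
#'   triggering domain names, empty when negative).
#' @export
classify_matts <- function(record, config) {
  stopifnot(inherits(config, "reference_standard_config"), nrow(record) == 1)
  flags <- matts_domain_flags(record, config)
  hit <- unlist(flags[1, ])
  list(positive = any(hit), domains = names(flags)[hit])
}

#' Classify records against all four reference standards
#'
#' Appends per-record classification columns: `iss` (computed from the
#' AIS-coded injuries), the primary consensus standard `matts_primary` with
#' a `matts_domains` trace, and the three secondary standards — `iss16`
#' (ISS at or above the configured threshold), `urgent_interventions` (the
#' critical-interventions domain alone) and `matts_no_open_fractures` (the
#' consensus standard re-evaluated with open-fracture-triggered injury
#' rules removed).
#'
#' By construction `urgent_interventions` and `matts_no_open_fractures`
#' each imply `matts_primary`.
#'
#' @param records Tibble of incident records.
#' @param config A [reference_standard_config()].
#' @return `records` with classification columns appended.
#' @export
classify_reference_standards <- function(records,
                                         config = reference_standard_config()) {
  stopifnot(inherits(config, "reference_standard_config"))
  flags <- matts_domain_flags(records, config)
  flags_noof <- matts_domain_flags(records, config, include_open_fracture_rules = FALSE)
  records |>
    add_iss() |>
    dplyr::mutate(
      matts_primary = flags$critical_interventions | flags$significant_injury |
        flags$multiple_injury | flags$capacity_to_benefit,
      matts_domains = purrr::map_chr(seq_len(nrow(flags)), function(i) {
        hit <- unlist(flags[i, ])
        paste(names(flags)[hit], collapse = ";")
      }),
      iss16 = .data$iss >= config$iss_threshold,
      urgent_interventions = flags$critical_interventions,
      matts_no_open_fractures = flags_noof$critical_interventions |
        flags_noof$significant_injury | flags_noof$multiple_injury |
        flags_noof$capacity_to_benefit)
}
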