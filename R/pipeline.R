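#' Characterise an analysis sample by reference-standard status
#'
#' Descriptive statistics in the shape conventionally reported for trauma
#' case-cohort samples: counts, age summaries and band shares, sex,
#' mechanism distribution, first-value vital-sign summaries, and (for
#' reference-positive records) ISS and urgent-intervention summaries.
#'
#' @param records Classified analysis-set tibble (after
#'   [classify_reference_standards()]).
#' @param reference Column name of the reference-standard flag.
#' @return Tidy tibble: `variable`, `category`, `status`, `value`.
#' @export
characterise_sample <- function(records, reference = "matts_primary") {
  ref <- records[[reference]]
  one_status <- function(d, status) {
    first_val <- function(sig) vapply(d$vitals, function(v)
      if (nrow(v) == 0) NA_real_ else v[[sig]][1], numeric(1))
    rows <- list(
      tibble::tibble(variable = "n", category = "records", value = nrow(d)),
      tibble::tibble(variable = "age_years",
                     category = c("median", "q25", "q75"),
                     value = as.numeric(quantile(d$age_years, c(0.5, 0.25, 0.75)))),
      tibble::tibble(variable = "age_group",
                     category = c("child_lt16", "adult_16_64", "elderly_65plus"),
                     value = c(mean(d$age_years < 16),
                               mean(d$age_years >= 16 & d$age_years < 65),
                               mean(d$age_years >= 65))),
      tibble::tibble(variable = "sex", category = "female",
                     value = mean(d$sex == "female")),
      tibble::tibble(variable = "mode", category = "penetrating",
                     value = mean(d$mode == "penetrating")),
      tibble::tibble(variable = "mechanism", category = mechanism_classes(),
                     value = as.numeric(table(factor(d$mechanism,
                       levels = mechanism_classes())) / nrow(d))),
      purrr::map_dfr(c("sbp", "rr", "spo2", "gcs"), function(sig) {
        x <- first_val(sig)
        tibble::tibble(variable = sig, category = c("median", "q25", "q75"),
                       value = as.numeric(quantile(x, c(0.5, 0.25, 0.75),
                                                   na.rm = TRUE)))
      }),
      tibble::tibble(variable = "hems_response", category = "yes",
                     value = mean(d$hems_response)))
    if (status == "positive") {
      d <- add_iss(d)
      rows <- c(rows, list(
        tibble::tibble(variable = "iss", category = c("median", "q25", "q75"),
                       value = as.numeric(quantile(d$iss, c(0.5, 0.25, 0.75)))),
        tibble::tibble(variable = "urgent_intervention", category = "yes",
                       value = mean(vapply(d$interventions, length, 1L) > 0))))
    }
    dplyr::mutate(dplyr::bind_rows(rows), status = status)
  }
  dplyr::bind_rows(one_status(records[ref, ], "positive"),
                   one_status(records[!ref, ], "negative"))
}

#' Round accuracy-metric columns half-up for presentation
#'
#' @param df Tibble with metric columns (`sensitivity`, `lr_pos`, ...).
#' @param digits Decimal places (default 2, the conventional table
#'   precision).
#' @return `df` with numeric metric columns rounded half-up.
#' @export
format_accuracy <- function(df, digits = 2) {
  cols <- intersect(names(df),
                    c("sensitivity", "sens_lcl", "sens_ucl",
                      "specificity", "spec_lcl", "spec_ucl",
                      "lr_pos", "lr_pos_lcl", "lr_pos_ucl",
                      "lr_neg", "lr_neg_lcl", "lr_neg_ucl"))
  dplyr::mutate(df, dplyr::across(dplyr::all_of(cols),
                                  ~ round_half_up(.x, digits)))
}

#' Recompute a published accuracy table from its printed counts
#'
#' Reads a counts CSV (columns `tp`, `fp`, `tn`, `fn` plus labels), applies
#' the estimator to every row, and presents the metrics at the printed
#' precision (round-half-up).
#'
#' @param path CSV path; defaults to the bundled published counts fixture.
#' @param digits Presentation precision; `NULL` for full precision.
#' @inheritParams estimate_accuracy
#' @return Tibble with counts and recomputed metrics.
#' @examples
#' head(report_from_counts())
#' @export
report_from_counts <- function(path = triage_counts_path(), digits = 2,
                               ci_method = "wilson") {
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  keep <- intersect(names(counts),
                    c("tool_number", "tool_name", "service", "depth", "type",
                      "n", "tp", "fp", "tn", "fn"))
  out <- accuracy_from_counts(counts[keep], ci_method = ci_method)
  if (!is.null(digits)) out <- format_accuracy(out, digits)
  out
}

#' Configure a full pipeline run
#'
#' @param population A [population_config()] or path to a YAML/JSON one.
#' @param tools List of [triage_tool()]s or file paths; defaults to the
#'   bundled example tools.
#' @param reference A [reference_standard_config()].
#' @param index_test `"prealert_mtc"` (transport to MTC with pre-alert, the
#'   primary index test) or `"destination_mtc"` (initial MTC destination).
#' @param subcohort_size Random sub-cohort size.
#' @param strata Age-band breaks for stratified analyses.
#' @param ci_method `"wilson"` or `"wald"`.
#' @param output_dir Directory for the report bundle.
#' @param seed Seed for the sampling stage.
#' @param make_plots Write ROC/stratified plots (PNG) into the bundle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(population = population_config(),
                       tools = example_tool_paths(),
                       reference = reference_standard_config(),
                       index_test = c("prealert_mtc", "destination_mtc"),
                       subcohort_size = 2000,
                       strata = age_bins(),
                       ci_method = c("wilson", "wald"),
                       output_dir = tempfile("triagecc-run-"),
                       seed = 1L,
                       make_plots = TRUE) {
  if (is.character(population)) population <- read_population_config(population)
  stopifnot(inherits(population, "population_config"))
  tools <- lapply(tools, function(t)
    if (is.character(t)) read_triage_tool(t) else t)
  if (!all(vapply(tools, inherits, TRUE, "triage_tool")))
    config_abort("tools", "must be triage_tool objects or file paths")
  stopifnot(inherits(reference, "reference_standard_config"))
  index_test <- match.arg(index_test)
  ci_method <- match.arg(ci_method)
  if (subcohort_size < 1 || subcohort_size > population$n_incidents)
    config_abort("subcohort_size", "must be between 1 and n_incidents")
  structure(list(population = population, tools = tools, reference = reference,
                 index_test = index_test, subcohort_size = subcohort_size,
                 strata = strata, ci_method = ci_method,
                 output_dir = output_dir, seed = as.integer(seed),
                 make_plots = make_plots),
            class = "run_config")
}

index_column <- function(index_test)
  switch(index_test, prealert_mtc = "provider_prealert_mtc",
         destination_mtc = "destination_mtc")

overall_metrics <- function(records, index, reference, ci_method) {
  ref <- records[[reference]]
  keep <- ref | records$in_subcohort
  idx <- records[[index]]
  safe_metrics(sum(idx & ref & keep), sum(idx & !ref & keep),
               sum(!idx & !ref & keep), sum(!idx & ref & keep), ci_method)
}

#' Run the full simulation-and-evaluation pipeline
#'
#' Executes the staged analysis on one synthetic cohort: (1) generate the
#' parent cohort; (2) extract registry cases and link them to ambulance
#' records on the report-form identifier; (3) draw the case-cohort
#' analysis sample; (4) apply the complete-case filter; (5) classify every
#' record against the four reference standards; (6) evaluate each triage
#' tool cumulatively; (7) estimate prevalence, observed-decision accuracy
#' (overall, per service, per age band), theoretical cumulative-step
#' accuracy per tool, and the sensitivity-analysis matrix of four
#' reference standards by two index tests; (8) write the report bundle
#' (tidy CSVs, optional plots) with a machine-readable JSON manifest
#' carrying the resolved configuration, stage-by-stage record accounting
#' and a content hash for every output file.
#'
#' Rerunning an identical configuration reproduces the bundle exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the analysis tibbles (`characteristics`,
#'   `prevalence`, `decision_overall`, `decision_by_service`,
#'   `decision_by_age`, `tool_steps`, `sensitivity_analyses`), the
#'   `records` analysis set, the `manifest` list and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- list()

  cohort <- generate_parent_cohort(config$population)
  stages$simulate <- list(records_in = config$population$n_incidents,
                          records_out = nrow(cohort),
                          truth_positive = sum(cohort$true_status))

  registry <- cohort[cohort$true_status,
                     c("record_id", "report_form_id", "true_status")]
  linkage <- link_records(registry, cohort)
  stages$linkage <- as.list(linkage$report)

  linked_positive <- cohort$record_id %in% linkage$matched$record_id
  sample_set <- draw_case_cohort_sample(cohort, config$subcohort_size,
                                        truth = linked_positive,
                                        seed = config$seed)
  stages$sample <- list(subcohort = sum(sample_set$in_subcohort),
                        cases = sum(sample_set$is_case),
                        cases_in_subcohort = sum(sample_set$is_case &
                                                   sample_set$in_subcohort),
                        analysis_set = nrow(sample_set))

  idx_col <- index_column(config$index_test)
  filtered <- apply_complete_case_filter(
    sample_set, required = c("age_years", "sex", "mechanism", "vitals", idx_col))
  stages$complete_case <- list(records_in = nrow(sample_set),
                               records_out = nrow(filtered),
                               removed = attr(filtered, "n_removed"),
                               by_field = as.list(setNames(
                                 complete_case_log(filtered)$removed,
                                 complete_case_log(filtered)$field)))

  records <- classify_reference_standards(filtered, config$reference)
  stages$classify <- list(matts_primary = sum(records$matts_primary),
                          iss16 = sum(records$iss16),
                          urgent_interventions = sum(records$urgent_interventions),
                          matts_no_open_fractures = sum(records$matts_no_open_fractures))

  prevalence <- estimate_prevalence(
    records$matts_primary[records$in_subcohort],
    ci_method = if (config$ci_method == "wilson") "wilson" else "wald")

  decision_overall <- dplyr::bind_cols(
    tibble::tibble(stratum = "overall"),
    overall_metrics(records, idx_col, "matts_primary", config$ci_method))
  decision_by_service <- stratified_accuracy(records, idx_col, "matts_primary",
                                             strata = "service",
                                             ci_method = config$ci_method)
  decision_by_age <- stratified_accuracy(records, idx_col, "matts_primary",
                                         strata = config$strata,
                                         ci_method = config$ci_method)

  tool_steps <- dplyr::bind_rows(lapply(config$tools, function(t)
    cumulative_step_series(records, t, "matts_primary", index = idx_col,
                           ci_method = config$ci_method)))

  refs <- c("matts_primary", "iss16", "urgent_interventions",
            "matts_no_open_fractures")
  idxs <- c("provider_prealert_mtc", "destination_mtc")
  sensitivity_analyses <- purrr::map_dfr(refs, function(r)
    purrr::map_dfr(idxs, function(ix) dplyr::bind_cols(
      tibble::tibble(reference = r, index_test = ix),
      overall_metrics(records, ix, r, config$ci_method))))

  characteristics <- characterise_sample(records, "matts_primary")

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_file <- function(name) file.path(config$output_dir, name)
  tables <- list(
    cohort_characteristics = characteristics,
    prevalence = prevalence,
    decision_accuracy_overall = decision_overall,
    decision_accuracy_by_service = decision_by_service,
    decision_accuracy_by_age = decision_by_age,
    tool_step_accuracy = tool_steps,
    sensitivity_analyses = sensitivity_analyses)
  paths <- character()
  for (nm in names(tables)) {
    p <- out_file(paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, na = "")
    paths[nm] <- p
  }
  if (isTRUE(config$make_plots)) {
    p1 <- out_file("roc_tool_steps.png")
    grDevices::png(p1, width = 1600, height = 1400, res = 200)
    print(plot_step_roc(tool_steps))
    grDevices::dev.off()
    p2 <- out_file("age_accuracy.png")
    grDevices::png(p2, width = 1800, height = 1200, res = 200)
    print(plot_age_accuracy(decision_by_age))
    grDevices::dev.off()
    paths["roc_tool_steps"] <- p1
    paths["age_accuracy"] <- p2
  }

  manifest <- list(
    package = "triagecc",
    version = as.character(utils::packageVersion("triagecc")),
    seed = config$seed,
    index_test = config$index_test,
    subcohort_size = config$subcohort_size,
    ci_method = config$ci_method,
    strata = config$strata,
    population = unclass(config$population),
    reference = unclass(config$reference),
    tools = vapply(config$tools, `[[`, "", "service_label"),
    stages = stages,
    files = lapply(seq_along(paths), function(i) list(
      name = basename(paths[[i]]),
      md5 = unname(tools::md5sum(paths[[i]])))))
  manifest_path <- out_file("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  invisible(c(tables, list(records = records, manifest = manifest,
                           manifest_path = manifest_path,
                           output_dir = config$output_dir)))
}
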