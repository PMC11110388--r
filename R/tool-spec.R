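#' Vocabulary of triage-tool criterion variables
#'
#' Physiological variables are evaluated against the recorded vital-sign
#' series (first value, or a sustained run); `age` against age in years;
#' `mechanism`, `injury_pattern` and `special_circumstance` are categorical
#' set-membership variables.
#'
#' @return Named list with `physiology`, `numeric` and `categorical`
#'   variable names.
#' @export
criterion_variables <- function() {
  list(physiology = c("sbp", "rr", "spo2", "gcs"),
       numeric = "age",
       categorical = c("mechanism", "injury_pattern", "special_circumstance"))
}

#' Canonical mechanism-of-injury classes
#' @return Character vector of the eleven mechanism categories.
#' @export
mechanism_classes <- function() {
  c("cutting_stabbing", "gunshot", "fall_gt_1m", "fall_lt_1m",
    "rta_motorcycle", "rta_motor_vehicle", "rta_bicycle", "rta_pedestrian",
    "struck_object", "struck_person", "other_unknown")
}

valid_comparators <- c("<", "<=", ">", ">=", "==", "in")

#' Define a single triage criterion
#'
#' @param variable One of the names in [criterion_variables()].
#' @param comparator One of `<`, `<=`, `>`, `>=`, `==` for numeric
#'   variables, or `"in"` (set membership) for categorical variables.
#' @param threshold Numeric cut-off, or a character vector of category
#'   labels for `"in"`.
#' @param sustained If `TRUE` (physiological variables only) the criterion
#'   requires two or more *consecutive* recorded measurements meeting the
#'   threshold; otherwise the first recorded value is used.
#' @param description Free-text label used in evidence traces.
#' @param path Internal; prefix for validation error messages.
#' @return Object of class `triage_criterion`.
#' @export
triage_criterion <- function(variable, comparator, threshold,
                             sustained = FALSE, description = "",
                             path = "criterion") {
  vars <- criterion_variables()
  fail <- function(field, msg)
    abort(sprintf("%s.%s: %s", path, field, msg), class = "triagecc_spec_error")
  if (!variable %in% unlist(vars))
    fail("variable", sprintf("unknown variable '%s'", variable))
  if (!comparator %in% valid_comparators)
    fail("comparator", sprintf("unknown comparator '%s'", comparator))
  categorical <- variable %in% vars$categorical
  if (categorical) {
    if (comparator != "in")
      fail("comparator", "categorical variables require the 'in' comparator")
    if (!is.character(threshold) || length(threshold) == 0)
      fail("threshold", "must be a non-empty character set for a categorical variable")
    if (variable == "mechanism" &&
        length(setdiff(threshold, mechanism_classes())) > 0)
      fail("threshold", sprintf("unknown mechanism class(es): %s",
                                paste(setdiff(threshold, mechanism_classes()), collapse = ", ")))
  } else {
    if (comparator == "in")
      fail("comparator", "'in' only applies to categorical variables")
    if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold))
      fail("threshold", "must be a single finite number for a numeric variable")
  }
  if (isTRUE(sustained) && !variable %in% vars$physiology)
    fail("sustained", "sustained thresholds apply to physiological variables only")
  structure(list(variable = variable, comparator = comparator,
                 threshold = threshold, sustained = isTRUE(sustained),
                 description = as.character(description)),
            class = "triage_criterion")
}

#' Define one step of a step-wise triage tool
#'
#' @param index Step number (1-4), or 1 for an ungrouped single checklist.
#' @param label One of `physiology`, `anatomy`, `mechanism`,
#'   `special_circumstances`, `ungrouped`.
#' @param mandatory Mandatory steps indicate bypass/pre-alert when positive;
#'   discretionary steps prompt consideration only.
#' @param criteria Non-empty list of [triage_criterion()] objects.
#' @param path Internal; prefix for validation error messages.
#' @return Object of class `triage_step`.
#' @export
triage_step <- function(index, label, mandatory, criteria, path = "step") {
  fail <- function(field, msg)
    abort(sprintf("%s.%s: %s", path, field, msg), class = "triagecc_spec_error")
  labels <- c("physiology", "anatomy", "mechanism", "special_circumstances", "ungrouped")
  if (!is.numeric(index) || index < 1 || index > 4) fail("index", "must be 1-4")
  if (!label %in% labels)
    fail("label", sprintf("must be one of %s", paste(labels, collapse = ", ")))
  if (!is.logical(mandatory) || length(mandatory) != 1) fail("mandatory", "must be TRUE/FALSE")
  if (length(criteria) == 0) fail("criteria", "step has no criteria")
  if (!all(vapply(criteria, inherits, TRUE, "triage_criterion")))
    fail("criteria", "all entries must be triage_criterion objects")
  structure(list(index = as.integer(index), label = label,
                 mandatory = mandatory, criteria = criteria),
            class = "triage_step")
}

#' Define a service's step-wise triage tool
#'
#' Grouped tools have up to four steps with physiology (step 1) and
#' anatomical injury (step 2) mandatory, mechanism (step 3) and special
#' circumstances (step 4) discretionary. Ungrouped tools are a single
#' checklist evaluated at one depth.
#'
#' @param service_label Service name (e.g. `"LAS"`).
#' @param steps List of [triage_step()]s with strictly increasing indices.
#' @param grouped `TRUE` for a stepped tool, `FALSE` for a single checklist.
#' @return Object of class `triage_tool`.
#' @export
triage_tool <- function(service_label, steps, grouped = TRUE) {
  fail <- function(msg) abort(sprintf("tool '%s': %s", service_label, msg),
                              class = "triagecc_spec_error")
  if (length(steps) == 0) fail("must have at least one step")
  if (!all(vapply(steps, inherits, TRUE, "triage_step")))
    fail("steps must be triage_step objects")
  idx <- vapply(steps, `[[`, 1L, "index")
  if (any(diff(idx) <= 0) && length(idx) > 1) fail("step indices must be strictly increasing")
  if (!grouped && length(steps) != 1) fail("an ungrouped tool has exactly one step")
  if (grouped) {
    for (s in steps) {
      if (s$index <= 2 && !s$mandatory)
        fail(sprintf("step %d must be mandatory in a grouped tool", s$index))
      if (s$index >= 3 && s$mandatory)
        fail(sprintf("step %d must be discretionary in a grouped tool", s$index))
    }
  }
  structure(list(service_label = service_label, steps = steps, grouped = grouped),
            class = "triage_tool")
}

#' @export
print.triage_tool <- function(x, ...) {
  cat(sprintf("<triage_tool> %s (%s, %d step%s)\n", x$service_label,
              if (x$grouped) "grouped" else "ungrouped", length(x$steps),
              if (length(x$steps) == 1) "" else "s"))
  for (s in x$steps) {
    cat(sprintf("  step %d [%s, %s]\n", s$index, s$label,
                if (s$mandatory) "mandatory" else "discretionary"))
    for (cr in s$criteria)
      cat(sprintf("    %s %s %s%s\n", cr$variable, cr$comparator,
                  paste(cr$threshold, collapse = ","),
                  if (cr$sustained) " (sustained)" else ""))
  }
  invisible(x)
}

tool_from_list <- function(doc, path = "tool") {
  fail <- function(p, msg) abort(sprintf("%s: %s", p, msg),
                                 class = "triagecc_spec_error")
  if (is.null(doc$service)) fail(paste0(path, ".service"), "missing service label")
  if (is.null(doc$steps) || length(doc$steps) == 0)
    fail(paste0(path, ".steps"), "missing or empty steps list")
  steps <- purrr::imap(doc$steps, function(s, i) {
    sp <- sprintf("%s.steps[%d]", path, i)
    if (is.null(s$criteria) || length(s$criteria) == 0)
      fail(paste0(sp, ".criteria"), "step has no criteria")
    crit <- purrr::imap(s$criteria, function(cr, j) {
      thr <- cr$threshold
      if (!is.null(thr) && is.list(thr)) thr <- unlist(thr)
      triage_criterion(cr$variable %||% "", cr$comparator %||% "",
                       thr %||% NA, cr$sustained %||% FALSE,
                       cr$description %||% "",
                       path = sprintf("%s.criteria[%d]", sp, j))
    })
    triage_step(s$index %||% i, s$label %||% "ungrouped",
                s$mandatory %||% TRUE, crit, path = sp)
  })
  triage_tool(doc$service, steps, grouped = doc$grouped %||% TRUE)
}

#' Load a triage-tool specification from a YAML or JSON document
#'
#' Validates the document against the tool schema; violations raise errors
#' that name the offending path (e.g. `tool.steps[2].criteria[1].threshold`).
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A validated [triage_tool()].
#' @seealso [write_triage_tool()], [example_tool_paths()]
#' @export
read_triage_tool <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  tool_from_list(doc, path = basename(path))
}

#' Serialise a triage tool back to YAML
#'
#' `read_triage_tool(write_triage_tool(tool, path))` round-trips to an
#' identical specification.
#'
#' @param tool A [triage_tool()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_triage_tool <- function(tool, path) {
  doc <- list(
    service = tool$service_label, grouped = tool$grouped,
    steps = lapply(tool$steps, function(s) list(
      index = s$index, label = s$label, mandatory = s$mandatory,
      criteria = lapply(s$criteria, function(cr) list(
        variable = cr$variable, comparator = cr$comparator,
        threshold = if (length(cr$threshold) > 1) as.list(cr$threshold) else cr$threshold,
        sustained = cr$sustained, description = cr$description)))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Paths of the bundled example triage tools
#'
#' Four editable fixture specifications mirroring the structure used by
#' English ambulance services — three grouped four-step tools (LAS, WMAS,
#' YAS) and one ungrouped single-checklist tool (SWAS) — populated with
#' conventional field-triage variables. The authentic deployed variable
#' lists are service documents not reproduced here: these fixtures are
#' synthetic placeholders with the right structure, and real evaluations
#' must supply the service's own specification files.
#'
#' @return Named character vector of YAML file paths.
#' @export
example_tool_paths <- function() {
  dir <- system.file("extdata", "tools", package = "triagecc", mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  setNames(files, toupper(sub("\\.yaml$", "", basename(files))))
}

#' Load the bundled example triage tools
#' @return Named list of [triage_tool()] objects.
#' @export
example_tools <- function() {
  lapply(example_tool_paths(), read_triage_tool)
}
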