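#' Configure the synthetic prehospital injury population
#'
#' Defaults emulate the published characteristics of acutely injured
#' patients conveyed by four English ambulance services: an elderly-skewed,
#' predominantly blunt-trauma population dominated by ground-level falls,
#' with low (about 3%) prevalence of major trauma under the consensus
#' reference standard, vital-sign and injury-severity distributions that
#' differ by reference-standard status (positive ISS centred on median 18,
#' IQR 13-25), and provider pre-alert behaviour with configurable
#' whole-sample sensitivity/specificity and an age trend.
#'
#' All probabilities must lie in `[0, 1]`; categorical weights must sum to
#' one (tolerance 1e-9); `prevalence` must be strictly inside (0, 1). With
#' a fixed `seed` the generated cohort is identical across calls.
#'
#' @param n_incidents Number of incident records in the parent cohort.
#' @param prevalence True fraction of reference-standard-positive records.
#' @param age_mixture Per-status child/adult/elderly band weights, band
#'   ranges (years), and the beta shape of the elderly band.
#' @param sex_female Per-status probability of female sex.
#' @param mechanism_probs Per-status weights over [mechanism_classes()].
#'   Mode of injury is derived: penetrating for cutting/stabbing and
#'   gunshot mechanisms, blunt otherwise.
#' @param vitals_params Per-status first-value distributions for SBP
#'   (mmHg), RR (/min), SpO2 (%) and GCS deficit; number-of-measurements
#'   weights (1-4 serial values); bounded-random-walk drift SDs; plausible
#'   physiological bounds.
#' @param injury_params Per-status AIS body-region marginal probabilities,
#'   severity weights (AIS 1-5 at generation; severity 6 is representable
#'   but not generated), open-fracture probability for extremity injuries
#'   of severity 2+, and the redraw cap used to keep generated positives
#'   consistent with the consensus reference standard.
#' @param provider_behaviour Target whole-sample sensitivity/specificity of
#'   the simulated pre-alert decision, with per-year logit slopes
#'   (`sens_slope` for positives, `fpr_slope` for the false-positive rate
#'   in negatives; both negative by default so sensitivity falls and
#'   specificity rises with age).
#' @param interventions Urgent-intervention probability per status and the
#'   label set drawn from.
#' @param hems_prob Per-status probability of a helicopter EMS response.
#' @param destination_extra_prob Probability that a record not pre-alerted
#'   is nevertheless conveyed to the MTC (e.g. it is the closest hospital),
#'   so that the destination index test is a superset of the pre-alert one.
#' @param id_missingness Fraction of records lacking the report-form
#'   linkage identifier.
#' @param vitals_missingness Fraction of records with no recorded vital
#'   signs (removed by the complete-case filter).
#' @param services Participating service labels, assigned uniformly.
#' @param seed Master seed; stage-level child seeds are derived from it.
#' @return Object of class `population_config`.
#' @export
population_config <- function(
    n_incidents = 20000,
    prevalence = 0.031,
    age_mixture = list(
      positive = c(child = 0.032, adult = 0.512, elderly = 0.456),
      negative = c(child = 0.066, adult = 0.358, elderly = 0.576),
      child_range = c(0, 16), adult_range = c(16, 65),
      elderly_range = c(65, 103), elderly_shape = c(2, 2)),
    sex_female = c(positive = 0.415, negative = 0.532),
    mechanism_probs = list(
      positive = c(cutting_stabbing = 0.058, gunshot = 0.001,
                   fall_gt_1m = 0.242, fall_lt_1m = 0.354,
                   rta_motorcycle = 0.042, rta_motor_vehicle = 0.079,
                   rta_bicycle = 0.031, rta_pedestrian = 0.112,
                   struck_object = 0.047, struck_person = 0.022,
                   other_unknown = 0.012),
      negative = c(cutting_stabbing = 0.022, gunshot = 0,
                   fall_gt_1m = 0.061, fall_lt_1m = 0.709,
                   rta_motorcycle = 0.011, rta_motor_vehicle = 0.037,
                   rta_bicycle = 0.012, rta_pedestrian = 0.025,
                   struck_object = 0.047, struck_person = 0.059,
                   other_unknown = 0.017)),
    vitals_params = list(
      positive = list(sbp = c(mean = 137, sd = 26.7), rr = c(mean = 20, sd = 3.7),
                      spo2 = c(mean = 96.5, sd = 3.7),
                      gcs_deficit = c(0.55, 0.20, 0.10, 0.05, 0.10)),
      negative = list(sbp = c(mean = 142, sd = 25.9), rr = c(mean = 18, sd = 3.0),
                      spo2 = c(mean = 97.5, sd = 2.2),
                      gcs_deficit = c(0.80, 0.12, 0.04, 0.02, 0.02)),
      n_measurements = c(0.15, 0.35, 0.30, 0.20),
      drift_sd = c(sbp = 8, rr = 2, spo2 = 1.5),
      bounds = list(sbp = c(40, 280), rr = c(0, 70), spo2 = c(50, 100))),
    injury_params = list(
      region_probs = list(
        positive = c(head = 0.53, face = 0.146, thorax = 0.402,
                     abdomen = 0.206, extremities = 0.504, external = 0.33),
        negative = c(head = 0.25, face = 0.08, thorax = 0.10,
                     abdomen = 0.04, extremities = 0.55, external = 0.25)),
      severity_probs = list(positive = c(0.03, 0.40, 0.45, 0.09, 0.03),
                            negative = c(0.70, 0.30, 0, 0, 0)),
      open_fracture_prob = c(positive = 0.12, negative = 0),
      max_redraws = 25L),
    provider_behaviour = list(sensitivity = 0.467, specificity = 0.945,
                              sens_slope = -0.032, fpr_slope = -0.02),
    interventions = list(
      urgent_prob = c(positive = 0.308, negative = 0),
      urgent_set = c("intubation", "thoracostomy", "blood_transfusion",
                     "emergency_surgery", "interventional_radiology")),
    hems_prob = c(positive = 0.193, negative = 0.013),
    destination_extra_prob = 0.15,
    id_missingness = 0.05,
    vitals_missingness = 0.03,
    services = c("LAS", "SWAS", "WMAS", "YAS"),
    seed = 2026L) {

  provider_behaviour <- as.list(provider_behaviour)
  if (!is.numeric(n_incidents) || length(n_incidents) != 1 || n_incidents < 1 ||
      n_incidents != floor(n_incidents))
    config_abort("n_incidents", "must be a positive integer")
  assert_prob(prevalence, "prevalence", open = TRUE)
  assert_weights(age_mixture$positive, "age_mixture$positive")
  assert_weights(age_mixture$negative, "age_mixture$negative")
  assert_prob(sex_female, "sex_female")
  for (st in c("positive", "negative")) {
    w <- mechanism_probs[[st]]
    if (!identical(sort(names(w)), sort(mechanism_classes())))
      config_abort(paste0("mechanism_probs$", st),
                   "must weight exactly the canonical mechanism classes")
    assert_weights(w, paste0("mechanism_probs$", st))
    assert_weights(vitals_params[[st]]$gcs_deficit,
                   paste0("vitals_params$", st, "$gcs_deficit"))
    assert_prob(injury_params$region_probs[[st]],
                paste0("injury_params$region_probs$", st))
    assert_weights(injury_params$severity_probs[[st]],
                   paste0("injury_params$severity_probs$", st))
  }
  assert_weights(vitals_params$n_measurements, "vitals_params$n_measurements")
  assert_prob(injury_params$open_fracture_prob, "injury_params$open_fracture_prob")
  pb <- provider_behaviour
  assert_prob(pb$sensitivity, "provider_behaviour$sensitivity", open = TRUE)
  assert_prob(pb$specificity, "provider_behaviour$specificity", open = TRUE)
  assert_prob(interventions$urgent_prob, "interventions$urgent_prob")
  assert_prob(hems_prob, "hems_prob")
  assert_prob(destination_extra_prob, "destination_extra_prob")
  assert_prob(id_missingness, "id_missingness")
  assert_prob(vitals_missingness, "vitals_missingness")
  if (length(services) < 1) config_abort("services", "must name at least one service")
  if (!is.numeric(seed) || length(seed) != 1)
    config_abort("seed", "must be a single integer")

  structure(list(
    n_incidents = as.integer(n_incidents), prevalence = prevalence,
    age_mixture = age_mixture, sex_female = sex_female,
    mechanism_probs = mechanism_probs, vitals_params = vitals_params,
    injury_params = injury_params, provider_behaviour = provider_behaviour,
    interventions = interventions, hems_prob = hems_prob,
    destination_extra_prob = destination_extra_prob,
    id_missingness = id_missingness, vitals_missingness = vitals_missingness,
    services = services, seed = as.integer(seed)
  ), class = "population_config")
}

#' Read a population configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of
#' [population_config()]; the fully resolved configuration is returned (and
#' is echoed into the run manifest by [run_pipeline()]).
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A validated `population_config`.
#' @export
read_population_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(population_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    config_abort(unknown[1], "is not a population_config field")
  # yaml reads named numeric vectors as lists; coerce leaves back, recursively
  normalise <- function(x) {
    if (!is.list(x)) return(x)
    if (length(x) > 0 && all(vapply(x, function(e)
      (is.numeric(e) || is.character(e) || is.logical(e)) && length(e) == 1, TRUE)))
      return(unlist(x))
    lapply(x, normalise)
  }
  do.call(population_config, lapply(doc, normalise))
}
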