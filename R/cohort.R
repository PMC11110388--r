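clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# continuous ages from the child/adult/elderly band mixture; the elderly
# band is beta-skewed so the whole-stratum median lands where observed
draw_ages <- function(n, weights, mix) {
  if (n == 0) return(numeric())
  band <- sample(1:3, n, replace = TRUE, prob = weights)
  age <- numeric(n)
  nb <- tabulate(band, 3)
  age[band == 1] <- runif(nb[1], mix$child_range[1], mix$child_range[2])
  age[band == 2] <- runif(nb[2], mix$adult_range[1], mix$adult_range[2])
  age[band == 3] <- mix$elderly_range[1] +
    diff(mix$elderly_range) * rbeta(nb[3], mix$elderly_shape[1], mix$elderly_shape[2])
  age
}

# serial vital-sign series: first value from a per-status truncated normal,
# later values a bounded random walk; GCS walks in integer steps
draw_vitals <- function(n, params, status_params) {
  n_meas <- sample(seq_along(params$n_measurements), n, replace = TRUE,
                   prob = params$n_measurements)
  first <- list(
    sbp = round(clip(rnorm(n, status_params$sbp[["mean"]], status_params$sbp[["sd"]]),
                     params$bounds$sbp[1], params$bounds$sbp[2])),
    rr = round(clip(rnorm(n, status_params$rr[["mean"]], status_params$rr[["sd"]]),
                    params$bounds$rr[1], params$bounds$rr[2])),
    spo2 = round(clip(rnorm(n, status_params$spo2[["mean"]], status_params$spo2[["sd"]]),
                      params$bounds$spo2[1], params$bounds$spo2[2])))
  deficit_levels <- c(0L, 1L, 2L, 3L, NA)  # slot 5 = severe, drawn uniformly 4..12
  d_idx <- sample(1:5, n, replace = TRUE, prob = status_params$gcs_deficit)
  deficit <- deficit_levels[d_idx]
  deficit[is.na(deficit)] <- sample(4:12, sum(is.na(deficit)), replace = TRUE)
  first$gcs <- clip(15L - deficit, 3L, 15L)

  K <- max(n_meas)
  sig <- list()
  for (s in c("sbp", "rr", "spo2")) {
    M <- matrix(NA_real_, n, K)
    M[, 1] <- first[[s]]
    if (K >= 2) for (j in 2:K) {
      M[, j] <- round(clip(M[, j - 1] + rnorm(n, 0, params$drift_sd[[s]]),
                           params$bounds[[s]][1], params$bounds[[s]][2]))
    }
    M[col(M) > n_meas] <- NA
    sig[[s]] <- M
  }
  G <- matrix(NA_real_, n, K)
  G[, 1] <- first$gcs
  if (K >= 2) for (j in 2:K) {
    G[, j] <- clip(G[, j - 1] + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                       prob = c(0.1, 0.8, 0.1)), 3, 15)
  }
  G[col(G) > n_meas] <- NA
  sig$gcs <- G

  long <- data.frame(
    id = rep(seq_len(n), each = K), minute = rep(10 * (seq_len(K) - 1), n),
    sbp = as.vector(t(sig$sbp)), rr = as.vector(t(sig$rr)),
    spo2 = as.vector(t(sig$spo2)), gcs = as.vector(t(sig$gcs)))
  long <- long[!is.na(long$sbp), ]
  out <- unname(split.data.frame(long[, -1], factor(long$id, levels = seq_len(n))))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

# does an injury set trigger the generator's notion of the default consensus
# standard (used only to keep simulated positives internally consistent)?
injury_triggers <- function(sev, region, open, age) {
  any(sev >= 4) ||
    any(sev >= 3 & region == "head") ||
    any(sev >= 2 & open) ||
    length(unique(region[sev >= 3])) >= 2 ||
    (age >= 65 && any(sev >= 3))
}

draw_injury_set <- function(region_probs, severity_probs, open_prob) {
  hit <- runif(6) < region_probs
  if (!any(hit)) hit[sample.int(6, 1, prob = region_probs)] <- TRUE
  regions <- iss_body_regions()[hit]
  sev <- sample.int(5, length(regions), replace = TRUE, prob = severity_probs)
  open <- regions == "extremities" & sev >= 2 & runif(length(regions)) < open_prob
  data.frame(region = regions, severity = sev, open_fracture = open)
}

#' Generate a parent cohort of synthetic incident records
#'
#' Draws `n_incidents` records whose reference-standard status is Bernoulli
#' with the configured prevalence and whose demographics, mechanism, serial
#' vital signs, AIS-coded injuries, interventions and provider pre-alert
#' decision are drawn from per-status distributions (see
#' [population_config()]). Injury sets for true positives are redrawn (up
#' to the configured cap, then augmented with an urgent intervention) until
#' they satisfy the default consensus reference standard, so that
#' rule-based classification of the generated records agrees with the
#' generative status. The provider decision is a logistic function of true
#' status and age whose intercepts are calibrated on the realised cohort so
#' the whole-sample expectation hits the configured sensitivity and
#' specificity targets exactly.
#'
#' The same configuration (including its seed) always yields an identical
#' cohort.
#'
#' @param config A [population_config()].
#' @return Tibble with one row per incident: identifiers, `service`,
#'   demographics, `mechanism`/`mode`, list-columns `vitals` (serial
#'   measurements), `injuries` (AIS-coded entries) and `interventions`,
#'   `hems_response`, the index-test observations `provider_prealert_mtc`
#'   and `destination_mtc`, and the generative `true_status`.
#' @examples
#' cohort <- generate_parent_cohort(population_config(n_incidents = 500, seed = 1))
#' mean(cohort$true_status)  # close to the configured prevalence
#' @export
generate_parent_cohort <- function(config) {
  stopifnot(inherits(config, "population_config"))
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    n <- config$n_incidents
    pos <- runif(n) < config$prevalence
    status <- ifelse(pos, "positive", "negative")

    age <- numeric(n)
    age[pos] <- draw_ages(sum(pos), config$age_mixture$positive, config$age_mixture)
    age[!pos] <- draw_ages(sum(!pos), config$age_mixture$negative, config$age_mixture)

    sex <- ifelse(runif(n) < config$sex_female[status], "female", "male")
    mech <- character(n)
    for (st in c("positive", "negative")) {
      idx <- status == st
      mech[idx] <- sample(mechanism_classes(), sum(idx), replace = TRUE,
                          prob = config$mechanism_probs[[st]][mechanism_classes()])
    }
    mode <- ifelse(mech %in% c("cutting_stabbing", "gunshot"), "penetrating", "blunt")

    vit <- vector("list", n)
    for (st in c("positive", "negative")) {
      idx <- which(status == st)
      if (length(idx))
        vit[idx] <- draw_vitals(length(idx), config$vitals_params,
                                config$vitals_params[[st]])
    }
    # a small fraction of records have no recorded vitals at all
    no_vitals <- runif(n) < config$vitals_missingness
    empty <- data.frame(minute = numeric(), sbp = numeric(), rr = numeric(),
                        spo2 = numeric(), gcs = numeric())
    vit[no_vitals] <- list(empty)

    urgent <- runif(n) < config$interventions$urgent_prob[status]
    ivn <- vector("list", n)
    ivn[seq_len(n)] <- list(character())
    uset <- config$interventions$urgent_set
    for (i in which(urgent))
      ivn[[i]] <- sample(uset, sample(1:2, 1))

    ip <- config$injury_params
    inj <- vector("list", n)
    empty_inj <- data.frame(region = character(), severity = integer(),
                            open_fracture = logical())
    neg_idx <- which(!pos)
    # negatives: minor injuries, possibly none
    has_inj <- runif(length(neg_idx)) < 0.8
    for (k in seq_along(neg_idx)) {
      i <- neg_idx[k]
      inj[[i]] <- if (!has_inj[k]) empty_inj else
        draw_injury_set(ip$region_probs$negative, ip$severity_probs$negative, 0)
    }
    # positives: redraw until the injury set (or an urgent intervention)
    # satisfies the default consensus standard
    for (i in which(pos)) {
      ok <- FALSE
      for (try in seq_len(ip$max_redraws)) {
        cand <- draw_injury_set(ip$region_probs$positive, ip$severity_probs$positive,
                                ip$open_fracture_prob[["positive"]])
        if (urgent[i] ||
            injury_triggers(cand$severity, cand$region, cand$open_fracture, age[i])) {
          ok <- TRUE; break
        }
      }
      if (!ok) { # guarantee consistency: record gains an urgent intervention
        ivn[[i]] <- sample(uset, 1)
      }
      inj[[i]] <- cand
    }

    hems <- runif(n) < config$hems_prob[status]

    # provider pre-alert: logistic in status and age with intercepts solved
    # on the realised cohort so whole-sample E[sens], E[spec] hit targets
    pb <- config$provider_behaviour
    p_alert <- numeric(n)
    if (any(pos)) {
      a1 <- uniroot(function(a) mean(plogis(a + pb$sens_slope * age[pos])) - pb$sensitivity,
                    c(-30, 30))$root
      p_alert[pos] <- plogis(a1 + pb$sens_slope * age[pos])
    }
    if (any(!pos)) {
      a0 <- uniroot(function(a) mean(plogis(a + pb$fpr_slope * age[!pos])) -
                      (1 - pb$specificity), c(-30, 30))$root
      p_alert[!pos] <- plogis(a0 + pb$fpr_slope * age[!pos])
    }
    prealert <- runif(n) < p_alert
    dest_mtc <- prealert | runif(n) < config$destination_extra_prob

    report_id <- sprintf("PRF%07d", seq_len(n))
    report_id[runif(n) < config$id_missingness] <- NA_character_

    tibble::tibble(
      record_id = sprintf("R%07d", seq_len(n)),
      report_form_id = report_id,
      service = sample(config$services, n, replace = TRUE),
      age_years = age, sex = sex, mechanism = mech, mode = mode,
      vitals = vit, injuries = inj, interventions = ivn,
      hems_response = hems,
      provider_prealert_mtc = prealert,
      destination_mtc = dest_mtc,
      true_status = pos)
  })
}

#' Remove records with missing data required for accuracy calculation
#'
#' Complete-case rule: a record is retained only if every field required by
#' the index test, tool evaluation and reference standard is present. The
#' removal count attributable to each field is recorded in the
#' `"filter_log"` attribute (see [complete_case_log()]); a record missing
#' several fields is attributed to each.
#'
#' @param records Tibble of incident records.
#' @param required Field names to enforce. `"vitals"` requires a non-empty
#'   vital-sign series; an individual signal name (`"sbp"`, `"rr"`,
#'   `"spo2"`, `"gcs"`) requires a usable (non-missing) first value of that
#'   signal.
#' @return Filtered tibble with a `filter_log` attribute.
#' @export
apply_complete_case_filter <- function(records,
                                       required = c("age_years", "sex", "mechanism",
                                                    "vitals", "provider_prealert_mtc")) {
  n <- nrow(records)
  miss <- matrix(FALSE, n, length(required), dimnames = list(NULL, required))
  signals <- c("sbp", "rr", "spo2", "gcs")
  for (f in required) {
    if (f %in% signals) {
      miss[, f] <- vapply(records$vitals, function(v)
        is.null(v) || nrow(v) == 0 || !f %in% names(v) || is.na(v[[f]][1]), TRUE)
      next
    }
    if (!f %in% names(records))
      abort(sprintf("required field '%s' not present in records", f),
            class = "triagecc_missing_data")
    miss[, f] <- if (f %in% c("vitals", "injuries", "interventions"))
      vapply(records[[f]], function(x) is.null(x) || nrow(as.data.frame(x)) == 0, TRUE)
    else is.na(records[[f]])
  }
  drop <- rowSums(miss) > 0
  log <- tibble::tibble(field = required, removed = unname(colSums(miss)))
  out <- records[!drop, ]
  attr(out, "filter_log") <- log
  attr(out, "n_removed") <- sum(drop)
  if (nrow(out) == 0) warn("complete-case filter removed every record")
  out
}

#' Per-field removal log of the complete-case filter
#' @param records A tibble returned by [apply_complete_case_filter()].
#' @return Tibble with columns `field` and `removed`.
#' @export
complete_case_log <- function(records) attr(records, "filter_log")
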