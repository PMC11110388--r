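# Independent brute-force oracles and small record builders used across the
# suite. Everything here is deliberately naive: plain loops, no shared code
# with the package internals beyond the public constructors.

make_record <- function(record_id = "r1", age = 40, sex = "male",
                        mechanism = "fall_lt_1m",
                        sbp = 120, rr = 16, spo2 = 98, gcs = 15,
                        injuries = NULL, interventions = character(),
                        hems = FALSE, prealert = FALSE, dest = prealert,
                        service = "LAS") {
  k <- max(length(sbp), length(rr), length(spo2), length(gcs))
  pad <- function(x) c(x, rep(x[length(x)], k - length(x)))
  mode <- if (mechanism %in% c("cutting_stabbing", "gunshot")) "penetrating" else "blunt"
  if (is.null(injuries))
    injuries <- data.frame(region = character(), severity = integer(),
                           open_fracture = logical())
  tibble::tibble(
    record_id = record_id, report_form_id = record_id, service = service,
    age_years = age, sex = sex, mechanism = mechanism, mode = mode,
    vitals = list(data.frame(minute = 10 * (seq_len(k) - 1), sbp = pad(sbp),
                             rr = pad(rr), spo2 = pad(spo2), gcs = pad(gcs))),
    injuries = list(injuries), interventions = list(interventions),
    hems_response = hems, provider_prealert_mtc = prealert,
    destination_mtc = dest, true_status = FALSE)
}

make_injuries <- function(regions, severities, open = rep(FALSE, length(regions))) {
  data.frame(region = regions, severity = as.integer(severities),
             open_fracture = open)
}

# ISS by definition, brute force: best subset of at most three distinct
# regions, scoring each subset as the sum of squared per-region AIS maxima
oracle_iss <- function(injuries) {
  if (nrow(injuries) == 0) return(0L)
  if (any(injuries$severity == 6)) return(75L)
  regions <- unique(injuries$region)
  maxima <- sapply(regions, function(r) max(injuries$severity[injuries$region == r]))
  best <- 0
  for (k in 1:min(3, length(maxima))) {
    subsets <- utils::combn(length(maxima), k)
    for (j in seq_len(ncol(subsets)))
      best <- max(best, sum(maxima[subsets[, j]]^2))
  }
  as.integer(min(75, best))
}

# naive single-criterion evaluator, enumerating every consecutive run for
# sustained thresholds
oracle_criterion <- function(rec, cr) {
  cmpf <- switch(cr$comparator, "<" = `<`, "<=" = `<=`, ">" = `>`,
                 ">=" = `>=`, "==" = `==`, "in" = NULL)
  v <- cr$variable
  if (v %in% c("sbp", "rr", "spo2", "gcs")) {
    x <- rec$vitals[[1]][[v]]
    if (!cr$sustained) return(isTRUE(cmpf(x[1], cr$threshold)))
    ok <- FALSE
    if (length(x) >= 2)
      for (s in 1:(length(x) - 1)) for (e in (s + 1):length(x))
        if (all(cmpf(x[s:e], cr$threshold))) ok <- TRUE
    return(ok)
  }
  if (v == "age") return(isTRUE(cmpf(rec$age_years, cr$threshold)))
  if (v == "mechanism") return(rec$mechanism %in% cr$threshold)
  if (v == "injury_pattern") {
    inj <- rec$injuries[[1]]
    pats <- character()
    if (rec$mode == "penetrating" && nrow(inj) > 0) {
      if (any(inj$region %in% c("thorax", "abdomen"))) pats <- c(pats, "penetrating_torso")
      if (any(inj$region %in% c("head", "face"))) pats <- c(pats, "penetrating_head_neck")
    }
    if (nrow(inj) > 0 && any(inj$open_fracture)) pats <- c(pats, "open_fracture")
    if (nrow(inj) > 0 && any(inj$region == "extremities" & inj$severity >= 3))
      pats <- c(pats, "severe_extremity_injury")
    return(any(pats %in% cr$threshold))
  }
  # special circumstances
  sc <- character()
  if (isTRUE(rec$hems_response)) sc <- c(sc, "hems_attendance")
  if (rec$age_years >= 65) sc <- c(sc, "older_adult")
  if (rec$age_years < 16) sc <- c(sc, "child")
  any(sc %in% cr$threshold)
}

# naive whole-tool evaluation for one record
oracle_tool <- function(rec, tool) {
  idx <- sapply(tool$steps, function(s) s$index)
  step_res <- logical(length(tool$steps))
  for (i in seq_along(tool$steps)) {
    res <- FALSE
    for (cr in tool$steps[[i]]$criteria)
      if (oracle_criterion(rec, cr)) res <- TRUE
    step_res[i] <- res
  }
  cumulative <- sapply(seq_len(max(idx)), function(k) any(step_res[idx <= k]))
  mand <- sapply(tool$steps, function(s) s$mandatory)
  list(steps = step_res, cumulative = cumulative,
       final_mandatory = any(step_res[mand]), final_all = any(step_res))
}

# random records exercising threshold boundaries, short/long series, all
# mechanism classes and injury patterns
fuzz_records <- function(n, seed) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(1:4, 1)
      make_record(
        record_id = sprintf("f%04d", i),
        age = sample(c(0:100, 15, 16, 64, 65, 90), 1),
        mechanism = sample(triagecc::mechanism_classes(), 1),
        sbp = sample(c(60:180, 89, 90, 91), k, replace = TRUE),
        rr = sample(c(4:45, 9, 10, 29, 30), k, replace = TRUE),
        spo2 = sample(c(70:100, 89, 90, 91, 92), k, replace = TRUE),
        gcs = sample(c(3:15, 8, 12, 13, 14), k, replace = TRUE),
        injuries = {
          m <- sample(0:3, 1)
          make_injuries(sample(triagecc::iss_body_regions(), m, replace = TRUE),
                        sample(1:5, m, replace = TRUE),
                        sample(c(TRUE, FALSE), m, replace = TRUE))
        },
        interventions = sample(c("intubation", "thoracostomy", "analgesia"),
                               sample(0:2, 1)),
        hems = runif(1) < 0.2, prealert = runif(1) < 0.3)
    })
    dplyr::bind_rows(rows)
  })
}

# one shared large calibrated cohort per test run (generation is the
# expensive step; several files check different properties of it)
.cohort_cache <- new.env(parent = emptyenv())
get_big_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    cfg <- triagecc::population_config(
      n_incidents = 50000,
      provider_behaviour = list(sensitivity = 0.47, specificity = 0.95,
                                sens_slope = -0.032, fpr_slope = -0.02),
      seed = 20260929)
    .cohort_cache$cohort <- triagecc::generate_parent_cohort(cfg)
  }
  .cohort_cache$cohort
}
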