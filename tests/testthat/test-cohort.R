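test_that("invalid population configurations are refused by field", {
  expect_error(population_config(prevalence = 0), "prevalence",
               class = "triagecc_config_error")
  expect_error(population_config(prevalence = 1), "prevalence",
               class = "triagecc_config_error")
  expect_error(population_config(n_incidents = 0), "n_incidents",
               class = "triagecc_config_error")
  expect_error(
    population_config(age_mixture = list(
      positive = c(child = 0.5, adult = 0.6, elderly = 0.2),
      negative = c(child = 0.066, adult = 0.358, elderly = 0.576),
      child_range = c(0, 16), adult_range = c(16, 65),
      elderly_range = c(65, 103), elderly_shape = c(2, 2))),
    "age_mixture", class = "triagecc_config_error")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- population_config(n_incidents = 400, seed = 99)
  expect_identical(generate_parent_cohort(cfg), generate_parent_cohort(cfg))
  cfg2 <- population_config(n_incidents = 400, seed = 100)
  expect_false(identical(generate_parent_cohort(cfg), generate_parent_cohort(cfg2)))
})

test_that("generated records respect the record invariants", {
  cohort <- generate_parent_cohort(population_config(n_incidents = 2000, seed = 5))
  expect_equal(nrow(cohort), 2000)
  expect_false(any(duplicated(cohort$record_id)))
  expect_true(all(cohort$age_years >= 0))
  expect_true(all(cohort$mechanism %in% mechanism_classes()))
  expect_identical(cohort$mode == "penetrating",
                   cohort$mechanism %in% c("cutting_stabbing", "gunshot"))
  vit <- dplyr::bind_rows(cohort$vitals)
  expect_true(all(vit$gcs >= 3 & vit$gcs <= 15))
  expect_true(all(vit$spo2 >= 0 & vit$spo2 <= 100))
  expect_true(all(vit$sbp > 0))
  inj <- dplyr::bind_rows(cohort$injuries)
  expect_true(all(inj$severity %in% 1:6))
  expect_true(all(inj$region %in% iss_body_regions()))
})

test_that("the negative stratum is dominated by ground-level falls", {
  cohort <- generate_parent_cohort(population_config(n_incidents = 20000, seed = 201))
  neg <- cohort[!cohort$true_status, ]
  expect_lt(abs(mean(neg$mechanism == "fall_lt_1m") - 0.709), 0.02)
})

test_that("large-cohort marginals converge to the configured targets", {
  cohort <- get_big_cohort()  # n = 50,000
  neg <- cohort[!cohort$true_status, ]
  pos <- cohort[cohort$true_status, ]
  expect_lt(abs(median(neg$age_years) - 73), 2)
  expect_lt(abs(median(pos$age_years) - 61), 3)
  iss <- add_iss(pos)$iss
  expect_lt(abs(median(iss) - 18), 1 + 1e-9)
  # prevalence recovery in a random sub-cohort, within binomial MC bounds
  sub <- draw_case_cohort_sample(cohort, 2000, seed = 17)
  p_hat <- mean(sub$is_case[sub$in_subcohort])
  expect_lt(abs(p_hat - 0.031), 1.96 * sqrt(0.031 * 0.969 / 2000))
})

test_that("complete-case filtering logs removals per field", {
  cohort <- generate_parent_cohort(
    population_config(n_incidents = 500, vitals_missingness = 0.2, seed = 8))
  cc <- apply_complete_case_filter(cohort)
  log <- complete_case_log(cc)
  expect_equal(sum(vapply(cohort$vitals, nrow, 1L) == 0),
               log$removed[log$field == "vitals"])
  expect_equal(nrow(cc) + attr(cc, "n_removed"), nrow(cohort))
  # a fully populated record is retained
  expect_true(make_record("keep")$record_id %in%
                apply_complete_case_filter(make_record("keep"))$record_id)
})

test_that("per-signal requirements attribute removals to the right signal", {
  recs <- dplyr::bind_rows(lapply(1:100, function(i) make_record(sprintf("r%03d", i))))
  for (i in 1:10) recs$vitals[[i]]$gcs <- NA_real_
  out <- apply_complete_case_filter(recs, required = c("age_years", "gcs"))
  expect_equal(nrow(out), 90)
  log <- complete_case_log(out)
  expect_equal(log$removed[log$field == "gcs"], 10)
  expect_equal(log$removed[log$field == "age_years"], 0)
})

test_that("case-cohort sampling keeps every case and respects the size", {
  cohort <- generate_parent_cohort(population_config(n_incidents = 1000, seed = 55))
  npos <- sum(cohort$true_status)
  s <- draw_case_cohort_sample(cohort, 200, seed = 1)
  expect_equal(sum(s$is_case), npos)
  expect_equal(sum(s$in_subcohort), 200)
  expect_lte(nrow(s), 200 + npos)
  expect_false(any(duplicated(s$record_id)))
  # positives drawn into the sub-cohort carry both provenance flags
  expect_true(any(s$in_subcohort & s$is_case) ||
                sum(s$is_case) + 200 == nrow(s))
  # saturation: sub-cohort the size of the cohort reproduces it
  full <- draw_case_cohort_sample(cohort, 1000, seed = 2)
  expect_equal(nrow(full), 1000)
  expect_true(all(full$in_subcohort))
  expect_error(draw_case_cohort_sample(cohort, 1001),
               class = "triagecc_config_error")
})

test_that("sub-cohort inclusion is uniform across records", {
  cohort <- generate_parent_cohort(population_config(n_incidents = 1000, seed = 56))
  hits <- numeric(1000)
  for (s in 1:500) {
    draw <- draw_case_cohort_sample(cohort, 200, seed = s)
    hits[cohort$record_id %in% draw$record_id[draw$in_subcohort]] <-
      hits[cohort$record_id %in% draw$record_id[draw$in_subcohort]] + 1
  }
  freq <- hits / 500
  expect_equal(mean(freq), 0.2, tolerance = 1e-12)  # each draw takes exactly 200
  # binomial(500, 0.2) Monte Carlo bound across 1,000 records
  expect_lt(max(abs(freq - 0.2)), 4.5 * sqrt(0.2 * 0.8 / 500))
})

test_that("deterministic linkage matches exactly and reports failures", {
  cohort <- generate_parent_cohort(
    population_config(n_incidents = 400, id_missingness = 0, seed = 77))
  cases <- cohort[cohort$true_status, ]
  res <- link_records(cases, cohort)
  expect_equal(res$report$match_rate, 1)
  # missing keys lower the match rate accordingly
  cohort5 <- generate_parent_cohort(
    population_config(n_incidents = 4000, id_missingness = 0.05, seed = 78))
  cases5 <- cohort5[cohort5$true_status, ]
  res5 <- link_records(cases5, cohort5)
  expect_gt(res5$report$match_rate, 0.85)
  expect_lt(res5$report$match_rate, 1)
  expect_equal(res5$report$unmatched_missing_key,
               sum(is.na(cases5$report_form_id)))
  # an ambiguous (duplicated) key is excluded from matching
  dup <- cohort[1:3, ]
  dup$report_form_id <- c("K1", "K1", "K2")
  one_case <- dup[1, ]
  amb <- link_records(one_case, dup)
  expect_equal(amb$report$matched, 0)
  expect_equal(amb$report$unmatched_ambiguous, 1)
})

test_that("records round-trip through CSV and JSON lines", {
  cohort <- generate_parent_cohort(population_config(n_incidents = 40, seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(cohort, csv)
  back <- read_records_csv(csv)
  expect_equal(back$record_id, cohort$record_id)
  expect_equal(back$age_years, cohort$age_years, tolerance = 1e-9)
  for (i in seq_len(nrow(cohort))) {
    expect_equal(back$vitals[[i]]$sbp, cohort$vitals[[i]]$sbp)
    expect_equal(back$injuries[[i]]$severity, cohort$injuries[[i]]$severity)
    expect_equal(back$interventions[[i]], cohort$interventions[[i]])
  }
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_records_jsonl(cohort, jl)
  back2 <- read_records_jsonl(jl)
  expect_equal(back2$record_id, cohort$record_id)
  expect_equal(back2$vitals[[5]], cohort$vitals[[5]], ignore_attr = TRUE)
})

test_that("population configuration round-trips through YAML", {
  cfg <- population_config(n_incidents = 123, prevalence = 0.05, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_incidents = 123, prevalence = 0.05, seed = 9), path)
  got <- read_population_config(path)
  expect_equal(got$n_incidents, 123L)
  expect_equal(got$prevalence, 0.05)
  expect_identical(generate_parent_cohort(got), generate_parent_cohort(cfg))
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(prevalnce = 0.05), bad)
  expect_error(read_population_config(bad), class = "triagecc_config_error")
})
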