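cfg <- reference_standard_config()

test_that("single consensus domains trigger classification", {
  # critical intervention alone
  r1 <- make_record(interventions = "intubation")
  c1 <- classify_matts(r1, cfg)
  expect_true(c1$positive)
  expect_identical(c1$domains, "critical_interventions")
  # nothing at all
  r0 <- make_record(age = 40)
  expect_false(classify_matts(r0, cfg)$positive)
  # significant single injury
  r2 <- make_record(injuries = make_injuries("thorax", 4))
  expect_true(classify_matts(r2, cfg)$positive)
  # multiple-injury burden: two regions at AIS 3
  r3 <- make_record(injuries = make_injuries(c("thorax", "abdomen"), c(3, 3)))
  c3 <- classify_matts(r3, cfg)
  expect_true(c3$positive)
  expect_true("multiple_injury" %in% c3$domains)
  # capacity to benefit: elderly with a serious injury
  r4 <- make_record(age = 80, injuries = make_injuries("thorax", 3))
  expect_true("capacity_to_benefit" %in% classify_matts(r4, cfg)$domains)
  # same injury in a younger adult triggers nothing
  r5 <- make_record(age = 40, injuries = make_injuries("thorax", 3))
  expect_false(classify_matts(r5, cfg)$positive)
})

test_that("secondary standards follow their definitions", {
  # ISS 18 (3,3 in two regions) without interventions
  r <- make_record(injuries = make_injuries(c("thorax", "abdomen"), c(3, 3)))
  out <- classify_reference_standards(r, cfg)
  expect_true(out$iss16)
  expect_false(out$urgent_interventions)
  expect_true(out$matts_primary)
  # ISS 9 with an urgent intervention: intervention domain only
  r2 <- make_record(injuries = make_injuries("head", 2), interventions = "thoracostomy")
  out2 <- classify_reference_standards(r2, cfg)
  expect_false(out2$iss16)
  expect_true(out2$urgent_interventions)
  expect_true(out2$matts_primary)
  # positive solely through an open-fracture rule
  r3 <- make_record(injuries = make_injuries("extremities", 2, open = TRUE))
  out3 <- classify_reference_standards(r3, cfg)
  expect_true(out3$matts_primary)
  expect_false(out3$matts_no_open_fractures)
})

test_that("implication lattice holds on fuzzed records", {
  recs <- fuzz_records(400, seed = 31)
  out <- classify_reference_standards(recs, cfg)
  expect_true(all(out$matts_primary[out$urgent_interventions]))
  expect_true(all(out$matts_primary[out$matts_no_open_fractures]))
  # domain trace agrees with the single-record classifier
  withr::with_seed(32, idx <- sample(nrow(recs), 40))
  for (i in idx) {
    single <- classify_matts(recs[i, ], cfg)
    expect_identical(out$matts_primary[i], single$positive)
    expect_identical(out$matts_domains[i], paste(single$domains, collapse = ";"))
  }
})

test_that("reference-standard configuration is validated", {
  expect_error(reference_standard_config(urgent_interventions = character()),
               class = "triagecc_config_error")
  expect_error(reference_standard_config(iss_threshold = -1),
               class = "triagecc_config_error")
  expect_error(reference_standard_config(
    significant_injury_rules = data.frame(region = "torso", min_severity = 3,
                                          open_fracture_only = FALSE)),
    "unknown region", class = "triagecc_config_error")
  expect_error(reference_standard_config(multiple_injury = list(min_regions = 2)),
               class = "triagecc_config_error")
})
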