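test_that("non-sustained physiology criteria use the first recorded value", {
  rec <- make_record(sbp = c(85, 110))
  expect_true(evaluate_criterion(rec, triage_criterion("sbp", "<", 90))$result)
  rec2 <- make_record(sbp = c(110, 85))
  expect_false(evaluate_criterion(rec2, triage_criterion("sbp", "<", 90))$result)
  rec3 <- make_record(gcs = 15)
  expect_false(evaluate_criterion(rec3, triage_criterion("gcs", "<=", 13))$result)
})

test_that("sustained criteria need two or more consecutive qualifying values", {
  crit <- triage_criterion("rr", ">", 29, sustained = TRUE)
  expect_false(evaluate_criterion(make_record(rr = c(31, 25, 33)), crit)$result)
  expect_true(evaluate_criterion(make_record(rr = c(31, 33, 25)), crit)$result)
  # a single measurement can never be sustained
  expect_false(evaluate_criterion(make_record(rr = 40), crit)$result)
})

test_that("comparators are applied exactly, with no implicit rounding", {
  rec <- make_record(sbp = 90)
  expect_false(evaluate_criterion(rec, triage_criterion("sbp", "<", 90))$result)
  expect_true(evaluate_criterion(rec, triage_criterion("sbp", "<=", 90))$result)
})

test_that("categorical criteria test set membership over derived labels", {
  rec <- make_record(mechanism = "cutting_stabbing",
                     injuries = make_injuries("thorax", 3))
  expect_true(evaluate_criterion(
    rec, triage_criterion("injury_pattern", "in", "penetrating_torso"))$result)
  expect_true(evaluate_criterion(
    rec, triage_criterion("mechanism", "in", c("cutting_stabbing", "gunshot")))$result)
  old <- make_record(age = 80)
  expect_true(evaluate_criterion(
    old, triage_criterion("special_circumstance", "in", "older_adult"))$result)
  expect_false(evaluate_criterion(
    old, triage_criterion("special_circumstance", "in", "hems_attendance"))$result)
})

test_that("a missing required variable raises an explicit error, not FALSE", {
  rec <- make_record()
  rec$vitals <- list(data.frame(minute = numeric(), sbp = numeric(), rr = numeric(),
                                spo2 = numeric(), gcs = numeric()))
  expect_error(evaluate_criterion(rec, triage_criterion("sbp", "<", 90)),
               class = "triagecc_missing_data")
  expect_error(evaluate_tool(rec, example_tools()$LAS),
               class = "triagecc_missing_data")
  skip_mode <- evaluate_tool(rec, example_tools()$LAS, mode = "criterion_skip")
  expect_true(skip_mode$skipped)
})

test_that("cumulative results follow OR logic over steps", {
  tool <- example_tools()$LAS
  # positive only on the anatomy step (step 2)
  rec <- make_record(mechanism = "cutting_stabbing",
                     injuries = make_injuries("abdomen", 3))
  ev <- evaluate_tool_cumulative(rec, tool)
  expect_false(ev$cumulative[["depth_1"]])
  expect_true(all(ev$cumulative[c("depth_2", "depth_3", "depth_4")]))
  expect_true(ev$final_mandatory)
  # negative everywhere
  quiet <- make_record(age = 40)
  ev0 <- evaluate_tool_cumulative(quiet, tool)
  expect_false(any(ev0$cumulative))
  expect_false(ev0$final_all_steps)
})

test_that("evidence names the measurements behind every positive criterion", {
  rec <- make_record(sbp = c(95, 85, 80))
  ev <- evaluate_criterion(rec, triage_criterion("sbp", "<", 90, sustained = TRUE))
  expect_true(ev$result)
  expect_equal(ev$evidence$satisfied, c(FALSE, TRUE, TRUE))
  full <- evaluate_tool_cumulative(rec, example_tools()$LAS)
  pos <- full$per_criterion[full$per_criterion$result, ]
  expect_true(all(vapply(pos$evidence, function(e) any(e$satisfied), TRUE)))
})

test_that("vectorised engine matches the naive per-record oracle on fuzzed records", {
  recs <- fuzz_records(250, seed = 77)
  for (tool in example_tools()) {
    ev <- evaluate_tool(recs, tool)
    for (i in seq_len(nrow(recs))) {
      o <- oracle_tool(recs[i, ], tool)
      depths <- grep("^cumulative_", names(ev), value = TRUE)
      expect_identical(unname(unlist(ev[i, depths])), o$cumulative)
      expect_identical(ev$final_mandatory[i], o$final_mandatory)
      expect_identical(ev$final_all_steps[i], o$final_all)
    }
  }
})

test_that("cumulative results are monotone and criterion order is irrelevant", {
  recs <- fuzz_records(150, seed = 78)
  tool <- example_tools()$LAS
  ev <- evaluate_tool(recs, tool)
  depths <- as.matrix(ev[, grep("^cumulative_", names(ev))])
  expect_true(all(depths[, -1] >= depths[, -ncol(depths)]))
  # permute criteria within each step
  shuffled <- tool
  withr::with_seed(9, {
    shuffled$steps <- lapply(tool$steps, function(s) {
      s$criteria <- s$criteria[sample(length(s$criteria))]
      s
    })
  })
  expect_identical(evaluate_tool(recs, shuffled), evaluate_tool(recs, tool))
})

test_that("tool documents validate with path-addressed errors and round-trip", {
  tools <- example_tools()
  expect_length(tools, 4)
  las <- tools$LAS
  expect_true(las$grouped)
  expect_length(las$steps, 4)
  expect_true(all(vapply(las$steps[1:2], `[[`, TRUE, "mandatory")))
  expect_false(any(vapply(las$steps[3:4], `[[`, TRUE, "mandatory")))
  expect_false(tools$SWAS$grouped)
  expect_length(tools$SWAS$steps, 1)

  # sustained only applies to physiology
  expect_error(triage_criterion("mechanism", "in", "fall_gt_1m", sustained = TRUE),
               "sustained", class = "triagecc_spec_error")
  expect_error(triage_criterion("sbpp", "<", 90), "unknown variable",
               class = "triagecc_spec_error")
  expect_error(triage_criterion("sbp", "in", 90), class = "triagecc_spec_error")
  expect_error(triage_criterion("mechanism", "in", "warp_core_breach"),
               "unknown mechanism", class = "triagecc_spec_error")
  expect_error(triage_step(1, "physiology", TRUE, list()), "no criteria",
               class = "triagecc_spec_error")
  expect_error(
    triage_tool("X", list(triage_step(1, "physiology", FALSE,
                                      list(triage_criterion("sbp", "<", 90))))),
    "mandatory", class = "triagecc_spec_error")

  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_triage_tool(las, tmp)
  expect_equal(read_triage_tool(tmp), las, ignore_attr = TRUE)
})
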