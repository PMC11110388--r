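test_that("2x2 construction matches direct enumeration on fuzzed flags", {
  withr::with_seed(12, {
    for (i in 1:50) {
      n <- sample(5:200, 1)
      idx <- runif(n) < runif(1)
      ref <- runif(n) < runif(1)
      t <- build_two_by_two(idx, ref)
      tp <- 0; fp <- 0; tn <- 0; fn <- 0
      for (j in seq_len(n)) {
        if (idx[j] && ref[j]) tp <- tp + 1
        if (idx[j] && !ref[j]) fp <- fp + 1
        if (!idx[j] && !ref[j]) tn <- tn + 1
        if (!idx[j] && ref[j]) fn <- fn + 1
      }
      expect_equal(c(t$tp, t$fp, t$tn, t$fn), c(tp, fp, tn, fn))
    }
  })
  expect_error(build_two_by_two(c(TRUE, FALSE), TRUE), class = "triagecc_table_error")
  expect_error(build_two_by_two(c(TRUE, NA), c(TRUE, FALSE)),
               class = "triagecc_table_error")
})

test_that("likelihood-ratio identities hold to machine precision", {
  withr::with_seed(13, {
    for (i in 1:100) {
      t <- two_by_two(sample(1:500, 1), sample(1:500, 1),
                      sample(1:500, 1), sample(1:500, 1))
      e <- estimate_accuracy(t)
      expect_equal(e$lr_pos * (1 - e$specificity), e$sensitivity, tolerance = 1e-12)
      expect_equal(e$lr_neg * e$specificity, 1 - e$sensitivity, tolerance = 1e-12)
    }
  })
})

test_that("degenerate margins are refused or flagged", {
  expect_error(estimate_accuracy(two_by_two(0, 5, 10, 0)), "sensitivity",
               class = "triagecc_margin_error")
  expect_error(estimate_accuracy(two_by_two(5, 0, 0, 5)), "specificity",
               class = "triagecc_margin_error")
  perfect <- estimate_accuracy(two_by_two(10, 0, 50, 5))
  expect_true(is.infinite(perfect$lr_pos))
  expect_true(perfect$lr_pos_infinite)
  expect_true(is.finite(perfect$lr_pos_ci[["lower"]]))
})

test_that("Wilson intervals achieve near-nominal coverage", {
  # margins of the pooled decision table: 959 positives at sens 0.47,
  # 1798 negatives at spec 0.95
  withr::with_seed(14, {
    for (p in list(c(0.47, 959), c(0.95, 1798))) {
      x <- rbinom(2000, p[2], p[1])
      covered <- vapply(x, function(xi) {
        ci <- triagecc:::ci_proportion(xi, p[2], method = "wilson")
        ci[["lower"]] <= p[1] && p[1] <= ci[["upper"]]
      }, TRUE)
      expect_gt(mean(covered), 0.93)
      expect_lt(mean(covered), 0.97)
    }
  })
})

test_that("sub-cohort prevalence is a simple proportion with valid CI coverage", {
  expect_equal(round_half_up(100 * estimate_prevalence(54, n = 1722)$prevalence, 1), 3.1)
  zero <- estimate_prevalence(0, n = 100)
  expect_equal(zero$prevalence, 0)
  expect_gte(zero$conf.low, 0)
  expect_error(estimate_prevalence(logical()), class = "triagecc_margin_error")
  withr::with_seed(15, {
    x <- rbinom(1000, 1800, 0.031)
    covered <- vapply(x, function(xi) {
      ci <- estimate_prevalence(xi, n = 1800)
      ci$conf.low <= 0.031 && 0.031 <= ci$conf.high
    }, TRUE)
    expect_gt(mean(covered), 0.92)
  })
})

test_that("post-test probability follows Bayes on the odds scale", {
  expect_equal(posttest_probability(0.3, 1), 0.3)  # LR 1 leaves belief unchanged
  p <- 0.1; lr <- 5
  odds <- p / (1 - p) * lr
  expect_equal(posttest_probability(p, lr), odds / (1 + odds), tolerance = 1e-15)
  expect_error(posttest_probability(0, 2), class = "triagecc_config_error")
  expect_error(posttest_probability(1, 2), class = "triagecc_config_error")
  expect_error(posttest_probability(0.1, -1), class = "triagecc_config_error")
})

test_that("on a simple random sample the post-test probability equals the PPV", {
  withr::with_seed(16, {
    for (i in 1:20) {
      t <- two_by_two(sample(5:50, 1), sample(5:50, 1),
                      sample(50:500, 1), sample(5:50, 1))
      prev <- (t$tp + t$fn) / (t$tp + t$fp + t$tn + t$fn)
      e <- estimate_accuracy(t)
      expect_equal(posttest_probability(prev, e$lr_pos),
                   unname(predictive_values(t)["ppv"]), tolerance = 1e-12)
    }
  })
})

test_that("predictive values from a case-cohort table warn about enrichment", {
  t <- two_by_two(50, 10, 500, 50, design = "case_cohort")
  expect_warning(predictive_values(t), class = "triagecc_ppv_warning")
  expect_no_warning(predictive_values(two_by_two(50, 10, 500, 50)))
})

test_that("stratified estimates pool back to the whole-sample table", {
  recs <- fuzz_records(300, seed = 41)
  recs$ref <- classify_reference_standards(recs)$matts_primary
  strata <- c(0, 50, Inf)
  out <- stratified_accuracy(recs, "provider_prealert_mtc", "ref", strata)
  expect_equal(nrow(out), 2)
  whole <- build_two_by_two(recs$provider_prealert_mtc, recs$ref)
  expect_equal(sum(out$tp), whole$tp)
  expect_equal(sum(out$fp), whole$fp)
  expect_equal(sum(out$tn), whole$tn)
  expect_equal(sum(out$fn), whole$fn)
  expect_error(stratified_accuracy(recs, "provider_prealert_mtc", "ref", c(0, 50, 40, Inf)),
               class = "triagecc_config_error")
})

test_that("a stratum without reference positives reports specificity only", {
  recs <- dplyr::bind_rows(
    make_record("a", age = 20, prealert = TRUE),
    make_record("b", age = 25),
    make_record("c", age = 70, prealert = TRUE,
                injuries = make_injuries("head", 4)))
  recs$ref <- classify_reference_standards(recs)$matts_primary
  out <- stratified_accuracy(recs, "provider_prealert_mtc", "ref", c(0, 50, Inf))
  young <- out[out$stratum == "<50", ]
  expect_true(is.na(young$sensitivity))
  expect_false(is.na(young$specificity))
})

test_that("presentation rounding is half-up at the printed precision", {
  expect_equal(round_half_up(6.125, 2), 6.13)
  expect_equal(round_half_up(0.565, 2), 0.57)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-6.125, 2), -6.13)
  expect_equal(round_half_up(3.1349, 1), 3.1)
})

test_that("tidy and glance expose the estimate as tibbles", {
  e <- estimate_accuracy(two_by_two(446, 95, 1703, 513, design = "case_cohort"))
  td <- tidy(e)
  expect_equal(td$metric, c("sensitivity", "specificity", "lr_pos", "lr_neg"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(e)
  expect_equal(g$n, 2757)
  expect_equal(g$design, "case_cohort")
})
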