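test_that("ISS handles the canonical worked cases", {
  expect_identical(compute_iss(make_injuries(character(), integer())), 0L)
  # region maxima head 4 / thorax 3 / extremities 2 -> 16 + 9 + 4
  expect_identical(
    compute_iss(make_injuries(c("head", "thorax", "extremities"), c(4, 3, 2))), 29L)
  # two injuries in one region: only the regional maximum counts
  expect_identical(compute_iss(make_injuries(c("thorax", "thorax"), c(3, 5))), 25L)
  # any unsurvivable (AIS 6) injury fixes the score at 75
  expect_identical(compute_iss(make_injuries(c("face", "head"), c(2, 6))), 75L)
  # more than three injured regions: only the worst three contribute
  expect_identical(
    compute_iss(make_injuries(c("head", "face", "thorax", "abdomen"),
                              c(5, 4, 3, 2))), 50L)
})

test_that("ISS rejects invalid severities and regions", {
  expect_error(compute_iss(make_injuries("head", 0)), class = "triagecc_config_error")
  expect_error(compute_iss(make_injuries("head", 7)), class = "triagecc_config_error")
  expect_error(compute_iss(data.frame(region = "torso", severity = 3)),
               class = "triagecc_config_error")
})

test_that("ISS equals the brute-force subset oracle on random injury sets", {
  withr::with_seed(404, {
    for (i in 1:300) {
      m <- sample(1:5, 1)
      inj <- make_injuries(sample(iss_body_regions(), m, replace = TRUE),
                           sample(1:6, m, replace = TRUE))
      expect_identical(compute_iss(inj), oracle_iss(inj))
    }
  })
})

test_that("adding an injury never decreases the ISS", {
  withr::with_seed(405, {
    for (i in 1:200) {
      m <- sample(1:4, 1)
      inj <- make_injuries(sample(iss_body_regions(), m, replace = TRUE),
                           sample(1:5, m, replace = TRUE))
      extra <- make_injuries(sample(iss_body_regions(), 1), sample(1:5, 1))
      expect_gte(compute_iss(rbind(inj, extra)), compute_iss(inj))
    }
  })
})

test_that("add_iss appends a per-record score", {
  recs <- dplyr::bind_rows(
    make_record("a", injuries = make_injuries("head", 4)),
    make_record("b"))
  expect_equal(add_iss(recs)$iss, c(16L, 0L))
})
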