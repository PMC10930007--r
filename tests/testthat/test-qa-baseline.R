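# longitudinal baselines and pass/warn/fail decisions

test_that("sd-criterion thresholds at 2 and 3 sample SDs", {
  b <- c(39, 40, 41, 40, 40)  # mean 40
  s <- sd(b)
  d1 <- qa_decide(40 + 0.5 * s, b, "sd")
  expect_equal(d1$status, "pass")
  d2 <- qa_decide(40 - 2.5 * s, b, "sd")
  expect_equal(d2$status, "warn")
  expect_equal(d2$deviation, -2.5)
  d3 <- qa_decide(40 - 4 * s, b, "sd")
  expect_equal(d3$status, "fail")
})

test_that("percent-criterion thresholds at 5% and 10% of the mean", {
  b <- rep(40, 3)
  expect_equal(qa_decide(41, b, "percent")$status, "pass")
  expect_equal(qa_decide(37.5, b, "percent")$status, "warn")   # 6.25%
  d <- qa_decide(35, b, "percent")
  expect_equal(d$status, "fail")                               # 12.5%
  expect_equal(d$deviation, -12.5)
})

test_that("auto picks percent for short baselines and sd otherwise", {
  short <- rep(40, 5); long <- rnorm(20, 40, 1)
  expect_equal(qa_decide(40, short, "auto")$criterion, "percent")
  expect_equal(qa_decide(40, long, "auto")$criterion, "sd")
})

test_that("insufficient baselines yield not-evaluable, distinct from pass", {
  expect_equal(qa_decide(40, numeric(0), "percent")$status, "not-evaluable")
  expect_equal(qa_decide(40, 40, "sd")$status, "not-evaluable")
  expect_equal(qa_decide(40, c(39, 41), "sd")$status, "pass")
})

test_that("status is monotone in |x - mean| and both criteria agree at the mean", {
  set.seed(61)
  b <- rnorm(15, 50, 2)
  mu <- mean(b)
  rank_of <- c(pass = 1, warn = 2, fail = 3)
  for (crit in c("sd", "percent")) {
    xs <- mu + seq(0, 30, length.out = 40)
    st <- rank_of[sapply(xs, function(x) qa_decide(x, b, crit)$status)]
    expect_true(all(diff(st) >= 0))
    expect_equal(qa_decide(mu, b, crit)$status, "pass")
  }
})

test_that("measurements append to the store and failed runs stay out of baselines", {
  store <- qa_store(withr::local_tempdir())
  vals <- c("peak_snr@VAP1" = 60, "peak_snr@VAS1" = 58)
  for (i in 1:3)
    qa_append(store, "torso:B1_T1", "elements", sprintf("2021-0%d-01", i),
              vals + i * 0.1)
  h <- qa_history(store, "torso:B1_T1", "elements")
  expect_equal(nrow(h), 6)
  expect_error(qa_append(store, "torso:B1_T1", "elements", "2021-01-01",
                         vals), "already recorded")

  # a failing measurement is recorded but not accepted
  bad <- c("peak_snr@VAP1" = 60, "peak_snr@VAS1" = 2)
  res <- evaluate_measurement(bad, store, "torso:B1_T1", "elements",
                              date = "2021-05-27", criteria = "percent",
                              record = TRUE)
  expect_equal(res$overall, "fail")
  expect_equal(res$decisions$status[res$decisions$key == "peak_snr@VAS1"],
               "fail")
  h2 <- qa_history(store, "torso:B1_T1", "elements", accepted_only = TRUE)
  expect_false("2021-05-27" %in% h2$date)
  # evaluation itself never mutates previously accepted entries
  expect_equal(h2[h2$date != "2021-05-27", ],
               h[h$date != "2021-05-27", ])
})

test_that("an empty store yields not-evaluable decisions everywhere", {
  store <- qa_store(withr::local_tempdir())
  res <- evaluate_measurement(c("snr@+110" = 40), store, "torso:X", "unfiltered")
  expect_equal(res$decisions$status, "not-evaluable")
  expect_equal(res$overall, "not-evaluable")
})

test_that("combined overall verdict needs a majority of failing slices to fail", {
  store <- qa_store(withr::local_tempdir())
  locs <- sprintf("snr@%+d", seq(-170, 170, by = 20))
  for (i in 1:3)
    qa_append(store, "torso:B_T", "unfiltered", sprintf("2020-0%d-01", i),
              setNames(rep(40, 18), locs))
  # 2 of 18 slices out of tolerance: warn, not fail
  v <- setNames(rep(40, 18), locs); v[1:2] <- 20
  r1 <- evaluate_measurement(v, store, "torso:B_T", "unfiltered",
                             criteria = "percent")
  expect_equal(r1$overall, "warn")
  # majority out of tolerance: fail
  v2 <- setNames(rep(20, 18), locs)
  r2 <- evaluate_measurement(v2, store, "torso:B_T", "unfiltered",
                             criteria = "percent")
  expect_equal(r2$overall, "fail")
})

test_that("coil comparison flags only values below the reference minimum", {
  store <- qa_store(withr::local_tempdir())
  for (i in 1:3)
    qa_append(store, "torso:OLD", "unfiltered", sprintf("2020-0%d-01", i),
              c("snr@+110" = 40 + i, "snr@+130" = 45 + i))
  cand <- c("snr@+110" = 50, "snr@+130" = 46)  # all above/equal to minima
  r <- compare_coils(cand, store, "torso:OLD", "torso:NEW", "unfiltered")
  expect_false(any(r$flagged))
  expect_equal(r$margin, c(9, 0))  # equality is not flagged
  low <- c("snr@+110" = 30, "snr@+130" = 50)
  r2 <- compare_coils(low, store, "torso:OLD", "torso:NEW", "unfiltered")
  expect_equal(r2$flagged, c(TRUE, FALSE))
  expect_error(compare_coils(cand, store, "torso:OLD", "headneck:NEW",
                             "unfiltered"), "type mismatch")
})
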