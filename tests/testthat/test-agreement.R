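test_that("quartiles follow the interpolated-rank convention", {
  expect_equal(score_quartiles(rep(9, 18)),
               c(q1 = 9, median = 9, q3 = 9))
  # six 1s, twelve 9s: ranks 5.25 / 9.5 / 13.75 all on constant runs
  expect_equal(score_quartiles(c(rep(1, 6), rep(9, 12))),
               c(q1 = 1, median = 9, q3 = 9))
  # nine 7s, nine 8s: median interpolates, q3 lands inside the 8s
  expect_equal(score_quartiles(c(rep(7, 9), rep(8, 9))),
               c(q1 = 7, median = 7.5, q3 = 8))
  expect_error(score_quartiles(integer(0)), "empty")
  expect_error(score_quartiles(c(3, 10)), "1\\.\\.9")
})

test_that("linear quartiles agree with the reference quantile estimator", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:25, 1)
    s <- sample(1:9, n, replace = TRUE)
    expect_equal(unname(score_quartiles(s)),
                 unname(stats::quantile(s, c(0.25, 0.5, 0.75), type = 7)))
  }
})

test_that("nearest-rank convention returns attained scores", {
  cfg <- agreement_config(quantile_method = "nearest")
  set.seed(7)
  for (i in 1:100) {
    s <- sample(1:9, sample(1:20, 1), replace = TRUE)
    q <- score_quartiles(s, cfg)
    expect_true(all(q %in% s))
    expect_true(q["q1"] <= q["median"] && q["median"] <= q["q3"])
  }
})

test_that("ipras matches direct substitution and attains its bound at centre 5", {
  expect_equal(ipras(3, 7), 2.35)
  expect_equal(ipras(9, 9), 8.35)
  expect_equal(ipras(1, 3), 6.85)
  expect_error(ipras(7, 3), "exceed")
  set.seed(1)
  for (i in 1:200) {
    q1 <- runif(1, 1, 9); q3 <- runif(1, q1, 9)
    v <- ipras(q1, q3)
    expect_gte(v, 2.35)
    expect_identical(v == 2.35, (q1 + q3) / 2 == 5)
  }
})

test_that("round classification applies the median/IPRAS rules", {
  r <- classify_round(rep(9, 18))
  expect_identical(r$status, "AGREE_HIGH")
  expect_equal(r$iqr, 0)
  expect_equal(r$ipras, 8.35)

  expect_identical(classify_round(rep(5, 18))$status, "NO_AGREEMENT")
  expect_identical(classify_round(rep(1, 18))$status, "AGREE_LOW")

  pol <- classify_round(c(rep(1, 6), rep(9, 12)))
  expect_identical(pol$status, "NO_AGREEMENT")
  expect_equal(pol$iqr, 8)
  expect_equal(pol$ipras, 2.35)
})

test_that("spread equal to IPRAS still counts as agreement", {
  # configure the threshold to land exactly on the observed IQR
  cfg <- agreement_config(ipras_base = 8, ipras_slope = 0)
  r <- classify_round(c(rep(1, 6), rep(9, 12)), cfg)
  expect_equal(r$iqr, r$ipras)
  expect_identical(r$status, "AGREE_HIGH")
  cfg2 <- agreement_config(ipras_base = 7.99, ipras_slope = 0)
  expect_identical(classify_round(c(rep(1, 6), rep(9, 12)), cfg2)$status,
                   "NO_AGREEMENT")
})

test_that("low medians agree regardless of spread unless the symmetric rule is on", {
  s <- c(rep(1, 12), rep(9, 6))  # median 1, IQR 8, IPRAS 2.35
  expect_identical(classify_round(s)$status, "AGREE_LOW")
  cfg <- agreement_config(symmetric_low_rule = TRUE)
  expect_identical(classify_round(s, cfg)$status, "NO_AGREEMENT")
})

test_that("every vote set maps to exactly one status, invariant to order", {
  set.seed(99)
  statuses <- c("AGREE_HIGH", "AGREE_LOW", "NO_AGREEMENT")
  for (i in 1:300) {
    s <- sample(1:9, sample(1:25, 1), replace = TRUE)
    r <- classify_round(s)
    expect_true(r$status %in% statuses)
    expect_identical(classify_round(s[sample.int(length(s))])$status, r$status)
    expect_true(r$q1 <= r$median && r$median <= r$q3)
    expect_gte(r$iqr, 0)
  }
})

test_that("shifting all scores up never turns high agreement into low", {
  set.seed(123)
  for (i in 1:300) {
    s <- sample(1:9, sample(3:20, 1), replace = TRUE)
    before <- classify_round(s)$status
    k <- sample(1:8, 1)
    after <- classify_round(pmin(9L, s + k))$status
    if (before == "AGREE_HIGH") expect_identical(after, "AGREE_HIGH")
    expect_false(before == "AGREE_HIGH" && after == "AGREE_LOW")
  }
})

test_that("the grouped fast path matches the per-code classifier", {
  set.seed(17)
  votes <- do.call(rbind, lapply(1:60, function(i) {
    make_votes(sprintf("%03d.%d", i, i %% 10), sample(1:9, 18, replace = TRUE))
  }))
  many <- delphicodes:::.classify_many(votes$code, votes$score)
  for (i in seq_len(nrow(many))) {
    one <- classify_round(votes$score[votes$code == many$code[i]])
    expect_identical(many$status[i], one$status)
    expect_equal(many$median[i], one$median)
    expect_equal(many$ipras[i], one$ipras)
  }
})

test_that("configuration files read back into the same rule", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("quantile_lo = 0.30", "quantile_hi = 0.70",
               "quantile_method = nearest", "ipras_base = 2.35",
               "symmetric_low_rule = true"), f)
  cfg <- read_agreement_config(f)
  expect_equal(cfg$quantile_lo, 0.30)
  expect_identical(cfg$quantile_method, "nearest")
  expect_true(cfg$symmetric_low_rule)
})
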