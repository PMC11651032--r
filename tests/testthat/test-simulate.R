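test_that("code generation is exact on the chapter mix and seed-stable", {
  cfg <- sim_config(n_codes = 100L,
                    chapter_mix = c(infectious = 0.5, injury = 0.5),
                    n_covid = 0L)
  a <- simulate_codes(cfg, seed = 7)
  b <- simulate_codes(cfg, seed = 7)
  expect_identical(a, b)
  expect_identical(as.integer(table(a$chapter_id)[c("infectious", "injury")]),
                   c(50L, 50L))
  expect_false(anyDuplicated(a$code) > 0)
  expect_false(anyNA(icd9_family(a$code)))
  c2 <- simulate_codes(cfg, seed = 8)
  expect_false(identical(a$code, c2$code))
})

test_that("an impossible chapter mix is rejected", {
  expect_error(sim_config(chapter_mix = c(infectious = 0.5, injury = 0.4)),
               "sum to 1")
  cfg <- sim_config(n_codes = 10L, chapter_mix = c(bogus = 1), n_covid = 0L)
  expect_error(simulate_codes(cfg), "not in the chapter table")
})

test_that("reviewers threshold the latent probability at 60%, boundary included", {
  latents <- data.frame(code = c("001.0", "002.0", "003.0"),
                        p_abx = c(0.60, 0.599, 0.95))
  cfg <- sim_config(reviewer_error_rate = 0)
  props <- simulate_reviewers(latents, cfg, seed = 1)
  expect_identical(props$final_proposal, c("include", "exclude", "include"))
  expect_false(any(props$adjudicated))
})

test_that("reviewer discordance matches the closed-form rate 2e(1-e)", {
  cfg <- sim_config(n_codes = 20000L, reviewer_error_rate = 0.5, n_covid = 0L)
  props <- simulate_reviewers(simulate_codes(cfg, seed = 3), cfg, seed = 4)
  frac <- mean(props$adjudicated)
  # 2 * 0.5 * 0.5 = 0.5; 4 binomial SEs ~ 0.014
  expect_lt(abs(frac - 0.5), 0.015)
  # adjudication invariants hold throughout
  expect_true(all(is.na(props$reviewer3) == !props$adjudicated))
  expect_identical(props$final_proposal[props$adjudicated],
                   props$reviewer3[props$adjudicated])
})

test_that("degenerate concordant regime reaches high agreement everywhere", {
  cfg <- concordant_config(n_codes = 300L)
  codes <- simulate_codes(cfg, seed = 5)
  props <- simulate_reviewers(codes, cfg, seed = 6)
  votes <- simulate_votes(props, codes, panel_profiles(cfg),
                          round_number = 1L, config = cfg, seed = 7)
  rec <- run_round(props$code, votes)
  expect_length(rec$carried_forward, 0L)
  expect_true(all(rec$results$status == "AGREE_HIGH"))
})

test_that("the contested fraction reappears as first-round non-agreement", {
  cfg <- sim_config(n_codes = 16000L, controversy_fraction = 0.004, n_covid = 0L)
  codes <- simulate_codes(cfg, seed = 8)
  props <- simulate_reviewers(codes, cfg, seed = 9)
  votes <- simulate_votes(props, codes, panel_profiles(cfg),
                          round_number = 1L, config = cfg, seed = 10)
  rec <- run_round(props$code, votes)
  carried <- length(rec$carried_forward)
  # binomial mean 64, sd 8: allow 4 sd
  expect_lt(abs(carried - 64), 32)
  # contested codes drive the non-agreement
  expect_true(mean(codes$contested[match(rec$carried_forward, codes$code)]) > 0.9)
})

test_that("severity shift biases scores but stays on the scale", {
  cfg <- sim_config(n_codes = 100L, severity_shift = -2L,
                    controversy_fraction = 0, reviewer_error_rate = 0,
                    concordance = 1, n_covid = 0L)
  codes <- simulate_codes(cfg, seed = 11)
  props <- simulate_reviewers(codes, cfg, seed = 12)
  votes <- simulate_votes(props, codes, panel_profiles(cfg),
                          round_number = 1L, config = cfg, seed = 13)
  expect_true(all(votes$score >= 1L & votes$score <= 9L))
  expect_lt(mean(votes$score), 8 - 1.5)  # shifted down from the mode-8 draw
})

test_that("a wrong-sized profile table is rejected", {
  cfg <- sim_config(n_codes = 10L, n_covid = 0L)
  codes <- simulate_codes(cfg, seed = 1)
  props <- simulate_reviewers(codes, cfg, seed = 2)
  prof <- panel_profiles(cfg)[1:5, ]
  expect_error(simulate_votes(props, codes, prof, config = cfg), "n_panelists")
})

test_that("later rounds contract contested panels toward consensus", {
  cfg <- sim_config(n_codes = 200L, controversy_fraction = 1, n_covid = 0L)
  codes <- simulate_codes(cfg, seed = 14)
  props <- simulate_reviewers(codes, cfg, seed = 15)
  prof <- panel_profiles(cfg)
  v1 <- simulate_votes(props, codes, prof, 1L, cfg, seed = 16)
  rec1 <- run_round(props$code, v1, 1L)
  expect_gt(length(rec1$carried_forward), 190L)  # round 1: everything contested
  v2 <- simulate_votes(props, codes, prof, 2L, cfg, seed = 17,
                       pending = rec1$carried_forward)
  rec2 <- run_round(rec1$carried_forward, v2, 2L)
  expect_length(rec2$carried_forward, 0L)
  # with convergence disabled the panels stay contested
  cfg0 <- sim_config(n_codes = 200L, controversy_fraction = 1,
                     convergence = 0, n_covid = 0L)
  v2b <- simulate_votes(props, codes, prof, 2L, cfg0, seed = 17,
                        pending = rec1$carried_forward)
  rec2b <- run_round(rec1$carried_forward, v2b, 2L)
  expect_gt(length(rec2b$carried_forward), 150L)
})

test_that("covid flags are metadata on the configured number of codes", {
  cfg <- sim_config(n_codes = 500L, n_covid = 17L)
  codes <- simulate_codes(cfg, seed = 18)
  expect_identical(sum(codes$is_covid), 17L)
  expect_true(all(codes$chapter_id[codes$is_covid] %in%
                    c("infectious", "respiratory")))
})
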