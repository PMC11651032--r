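test_that("final direction composes proposal with agreement polarity", {
  expect_identical(resolve_direction("include", "AGREE_HIGH"), "include")
  expect_identical(resolve_direction("exclude", "AGREE_HIGH"), "exclude")
  expect_identical(resolve_direction("include", "AGREE_LOW"), "exclude")
  expect_identical(resolve_direction("exclude", "AGREE_LOW"), "include")
  cfg <- delphi_config(low_agreement = "reclassify_exclude")
  expect_identical(resolve_direction("exclude", "AGREE_LOW", cfg), "exclude")
  expect_error(resolve_direction("include", "NO_AGREEMENT"), "AGREE")
})

test_that("a round classifies pending codes and carries forward dissent", {
  codes <- sprintf("00%d.0", 1:5)
  scores <- stats::setNames(rep(list(rep(9, 18)), 5), codes)
  rec <- run_round(codes, make_round(scores))
  expect_identical(length(rec$carried_forward), 0L)
  expect_setequal(rec$evaluated_codes, codes)

  scores[["003.0"]] <- c(rep(1, 6), rep(9, 12))
  rec2 <- run_round(codes, make_round(scores))
  expect_identical(rec2$carried_forward, "003.0")
  expect_identical(rec2$results$status[rec2$results$code == "003.0"],
                   "NO_AGREEMENT")
})

test_that("rounds reject votes for non-pending codes and missing votes", {
  votes <- make_round(list("001.0" = rep(9, 3), "002.0" = rep(9, 3)))
  expect_error(run_round("001.0", votes), "not pending")
  expect_error(run_round(c("001.0", "002.0", "003.0"), votes), "no round-1 votes")
  cfg <- delphi_config(mode = "permissive")
  expect_warning(rec <- run_round(c("001.0", "002.0", "003.0"), votes, config = cfg),
                 "003.0")
  expect_setequal(rec$evaluated_codes, c("001.0", "002.0"))
})

test_that("the engine iterates to full consensus and keeps history", {
  codes <- c("008.45", "941.20", "480.1")
  proposals <- cbind(data.frame(code = codes),
                     adjudicate(rep("include", 3), rep("include", 3)))
  r1 <- make_round(list("008.45" = rep(9, 18),
                        "941.20" = rep(2, 18),
                        "480.1" = rep(5, 18)), round = 1L)
  r2 <- make_round(list("480.1" = rep(8, 18)), round = 2L)
  out <- run_delphi(proposals, vote_source_from_rounds(list(r1, r2)))
  expect_true(out$complete)
  expect_identical(out$rounds_used, 2L)
  expect_length(out$history, 2L)
  fin <- out$final
  expect_identical(fin$classification[fin$code == "008.45"], "include")
  # unanimous rejection overturns the inclusion proposal
  expect_identical(fin$classification[fin$code == "941.20"], "exclude")
  expect_identical(fin$settling_round[fin$code == "480.1"], 2L)
  # round 2 evaluated exactly round 1's carry-forward
  expect_identical(out$history[[2]]$evaluated_codes,
                   out$history[[1]]$carried_forward)
})

test_that("an unresolvable code yields an explicit partial outcome", {
  proposals <- cbind(data.frame(code = "008.45"),
                     adjudicate("include", "include"))
  stubborn <- function(round, pending) {
    make_votes("008.45", rep(5, 18), round = round)
  }
  out <- run_delphi(proposals, stubborn, delphi_config(max_rounds = 3L))
  expect_false(out$complete)
  expect_identical(out$unresolved, "008.45")
  expect_identical(out$rounds_used, 3L)
  expect_identical(out$final$status, "UNRESOLVED")
  expect_true(is.na(out$final$classification))
})

test_that("outcomes conserve codes and are deterministic under seed", {
  cfg <- sim_config(n_codes = 400L, controversy_fraction = 0.02, n_covid = 0L)
  a <- simulate_delphi_study(cfg, seed = 21)
  b <- simulate_delphi_study(cfg, seed = 21)
  expect_identical(a$outcome$final, b$outcome$final)
  fin <- a$outcome$final
  n_inc <- sum(fin$classification == "include", na.rm = TRUE)
  n_exc <- sum(fin$classification == "exclude", na.rm = TRUE)
  expect_identical(n_inc + n_exc + length(a$outcome$unresolved), nrow(fin))
  expect_setequal(fin$code, a$proposals$code)
})

test_that("settling rounds agree with the recorded history", {
  cfg <- sim_config(n_codes = 300L, controversy_fraction = 0.05, n_covid = 0L)
  st <- simulate_delphi_study(cfg, seed = 31)
  fin <- st$outcome$final
  for (rec in st$outcome$history) {
    agreed <- rec$results$code[rec$results$status != "NO_AGREEMENT"]
    expect_identical(sort(fin$code[!is.na(fin$settling_round) &
                                     fin$settling_round == rec$round_number]),
                     sort(agreed))
  }
})

test_that("a concordant panel recovers the planted inclusion fraction exactly", {
  cfg <- concordant_config(n_codes = 500L)
  st <- simulate_delphi_study(cfg, seed = 41)
  truth <- ifelse(st$codes$p_abx >= cfg$proposal_threshold, "include", "exclude")
  fin <- st$outcome$final[match(st$codes$code, st$outcome$final$code), ]
  expect_identical(fin$classification, truth)
  expect_identical(st$outcome$rounds_used, 1L)
})

test_that("outcome files are written and reread consistently", {
  cfg <- sim_config(n_codes = 50L, controversy_fraction = 0.05, n_covid = 0L)
  st <- simulate_delphi_study(cfg, seed = 51)
  d <- withr::local_tempdir()
  write_outcome(st$outcome, d)
  fin <- utils::read.csv(file.path(d, "final_classification.csv"),
                         colClasses = c(code = "character"))
  expect_identical(nrow(fin), 50L)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(man$total_codes, 50L)
  expect_identical(man$rounds_used, st$outcome$rounds_used)
  expect_true(file.exists(file.path(d, "round_1_results.csv")))
})
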