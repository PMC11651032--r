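# Synthetic code universes, reviewer proposals, and panel votes with the
# statistical structure the consensus procedure assumes, so every stage
# is testable without the confidential panel data.
#
# The generative model: each code carries a latent probability p_abx that
# an admission coded with it receives systemic antimicrobial therapy.
# Reviewers threshold p_abx at 0.60 ("at least 60% of stays"), with an
# error rate; discordant pairs get an error-free third adjudication.
# Panelists endorse correct proposals (scores massed on 7..9) and reject
# incorrect ones (scores massed on 1..3); a small configured fraction of
# codes is genuinely contested and draws centred or polarized scores that
# fail the first-round agreement rule. Later rounds contract scores
# toward a majority-side consensus target.

.default_chapter_mix <- c(
  infectious = 0.070, neoplasms = 0.075, endocrine = 0.045, blood = 0.015,
  mental = 0.040, nervous = 0.065, circulatory = 0.065, respiratory = 0.040,
  digestive = 0.060, genitourinary = 0.050, pregnancy = 0.060, skin = 0.025,
  musculoskeletal = 0.055, congenital = 0.050, perinatal = 0.030,
  symptoms = 0.040, injury = 0.130, supp_v = 0.060, supp_e = 0.025
)

# Chapters whose conditions commonly carry systemic antimicrobial therapy
# draw p_abx from the high Beta mode with elevated weight; weights chosen
# so the expected inclusion fraction and the included set's chapter
# composition resemble a large hospital-discharge code universe
# (~18% inclusion, dominated by injury/poisoning and infectious codes).
.default_high_weight <- c(infectious = 0.98, injury = 0.54, pregnancy = 0.19)

#' Simulation configuration
#'
#' Defaults replicate the study conditions: 16,227 codes voted by an
#' 18-member panel, a 0.60 antimicrobial-administration threshold for the
#' inclusion proposal, and a contested fraction of 69/16227 (~0.43%) of
#' codes failing first-round agreement.
#'
#' @param n_codes Number of codes in the universe (default 16227).
#' @param chapter_mix Named vector of chapter proportions (must sum to 1;
#'   names are `chapter_id`s of [icd9_chapters()]).
#' @param p_abx_high,p_abx_low `c(shape1, shape2)` of the high and low
#'   Beta modes of the latent antimicrobial-administration probability.
#' @param high_weight Named vector of per-chapter mixture weights on the
#'   high mode; chapters not named use `high_weight_default`.
#' @param high_weight_default Baseline high-mode weight (default 0.053).
#' @param proposal_threshold Inclusion threshold on `p_abx`
#'   (default 0.60, "at least 60% of stays"; the boundary itself is
#'   included).
#' @param reviewer_error_rate Independent per-reviewer misclassification
#'   probability (default 0.03).
#' @param n_panelists Panel size (default 18).
#' @param concordance Probability that a panelist endorses a correct
#'   proposal (and rejects an incorrect one; default 0.98).
#' @param severity_shift Integer per-panelist bias in -2..2 added to
#'   drawn scores before clipping to 1..9 (scalar or length
#'   `n_panelists`; default 0).
#' @param controversy_fraction Fraction of codes that are genuinely
#'   contested (default 69/16227).
#' @param contested_style `"centered"` (scores massed on 4..6, default)
#'   or `"polarized"` (mass on both tails).
#' @param contested_endorse_prob Probability that a contested code's
#'   panel eventually converges toward endorsing (rather than rejecting)
#'   the proposal (default 0.6).
#' @param convergence Per-round contraction of later-round scores toward
#'   the majority-side consensus target, in `[0, 1]` (default 0.8; 0
#'   disables convergence).
#' @param score_endorse,score_reject,score_contested Probability vectors
#'   over scores 1..9 for endorsing, rejecting, and contested draws.
#' @param n_covid Number of codes flagged as 2020 SARS-CoV-2 additions
#'   (default 17; metadata only).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_codes = 16227L,
                       chapter_mix = .default_chapter_mix,
                       p_abx_high = c(10, 2), p_abx_low = c(1.5, 8),
                       high_weight = .default_high_weight,
                       high_weight_default = 0.053,
                       proposal_threshold = 0.60,
                       reviewer_error_rate = 0.03,
                       n_panelists = 18L,
                       concordance = 0.98,
                       severity_shift = 0L,
                       controversy_fraction = 69 / 16227,
                       contested_style = c("centered", "polarized"),
                       contested_endorse_prob = 0.6,
                       convergence = 0.8,
                       score_endorse = c(0, 0, 0, 0, 0, 0, 0.25, 0.50, 0.25),
                       score_reject = c(0.25, 0.50, 0.25, 0, 0, 0, 0, 0, 0),
                       score_contested = NULL,
                       n_covid = 17L) {
  contested_style <- match.arg(contested_style)
  if (is.null(score_contested)) {
    score_contested <- if (contested_style == "centered") {
      c(0.02, 0.05, 0.08, 0.18, 0.30, 0.18, 0.09, 0.06, 0.04)
    } else {
      c(0.20, 0.16, 0.08, 0.03, 0.02, 0.03, 0.10, 0.18, 0.20)
    }
  }
  if (abs(sum(chapter_mix) - 1) > 1e-6) {
    stop("chapter_mix proportions must sum to 1 (got ",
         format(sum(chapter_mix)), ")")
  }
  if (is.null(names(chapter_mix))) stop("chapter_mix must be named by chapter_id")
  for (v in list(score_endorse, score_reject, score_contested)) {
    if (length(v) != 9L || any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      stop("score distributions must be length-9 probability vectors")
    }
  }
  stopifnot(n_codes >= 1, n_panelists >= 1,
            proposal_threshold >= 0, proposal_threshold <= 1,
            reviewer_error_rate >= 0, reviewer_error_rate <= 1,
            concordance >= 0, concordance <= 1,
            controversy_fraction >= 0, controversy_fraction <= 1,
            convergence >= 0, convergence <= 1,
            all(severity_shift >= -2), all(severity_shift <= 2))
  structure(
    list(n_codes = as.integer(n_codes), chapter_mix = chapter_mix,
         p_abx_high = p_abx_high, p_abx_low = p_abx_low,
         high_weight = high_weight,
         high_weight_default = high_weight_default,
         proposal_threshold = proposal_threshold,
         reviewer_error_rate = reviewer_error_rate,
         n_panelists = as.integer(n_panelists),
         concordance = concordance,
         severity_shift = as.integer(severity_shift),
         controversy_fraction = controversy_fraction,
         contested_style = contested_style,
         contested_endorse_prob = contested_endorse_prob,
         convergence = convergence,
         score_endorse = score_endorse, score_reject = score_reject,
         score_contested = score_contested,
         n_covid = as.integer(n_covid)),
    class = "sim_config"
  )
}

# Largest-remainder apportionment of n over proportions p (exact when
# n * p is integral).
.apportion <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# All syntactically valid codes under a chapter's prefix range.
.chapter_pool <- function(chapter_row) {
  if (chapter_row$family == "numeric") {
    prefixes <- sprintf("%03d",
                        seq(as.integer(chapter_row$prefix_start),
                            as.integer(chapter_row$prefix_end)))
    ext <- c("", sprintf(".%d", 0:9), sprintf(".%02d", 0:99))
  } else if (chapter_row$family == "V") {
    lo <- as.integer(sub("V", "", chapter_row$prefix_start))
    hi <- as.integer(sub("V", "", chapter_row$prefix_end))
    prefixes <- sprintf("V%02d", seq(lo, hi))
    ext <- c("", sprintf(".%d", 0:9), sprintf(".%02d", 0:99))
  } else {
    lo <- as.integer(sub("E", "", chapter_row$prefix_start))
    hi <- as.integer(sub("E", "", chapter_row$prefix_end))
    prefixes <- sprintf("E%03d", seq(lo, hi))
    ext <- c("", sprintf(".%d", 0:9))
  }
  as.vector(outer(prefixes, ext, paste0))
}

#' Simulate an ICD-9-CM-shaped code universe with latent truth
#'
#' Generates `n_codes` syntactically valid, distinct identifiers
#' distributed over chapters per `chapter_mix` (largest-remainder
#' apportionment: exact when the products are integral), draws each
#' code's latent antimicrobial-administration probability `p_abx` from a
#' chapter-weighted two-mode Beta mixture, flags a configured fraction as
#' contested, and marks `n_covid` codes as SARS-CoV-2 additions
#' (metadata only). Fully reproducible under `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param chapters Chapter table (see [icd9_chapters()]).
#' @return A data.frame with columns `code`, `description`, `chapter_id`,
#'   `is_covid`, `p_abx`, `contested`, `contested_endorse`.
#' @export
simulate_codes <- function(config = sim_config(), seed = 1L,
                           chapters = icd9_chapters()) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(names(config$chapter_mix), chapters$chapter_id)
  if (length(unknown) > 0L) {
    stop("chapter_mix names not in the chapter table: ",
         paste(sQuote(unknown), collapse = ", "))
  }
  set.seed(seed)
  counts <- .apportion(config$n_codes, config$chapter_mix)
  names(counts) <- names(config$chapter_mix)
  pieces <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    id <- names(counts)[i]
    k <- counts[i]
    if (k == 0L) next
    pool <- .chapter_pool(chapters[chapters$chapter_id == id, , drop = FALSE])
    if (k > length(pool)) {
      stop("chapter ", sQuote(id), " cannot hold ", k, " distinct codes")
    }
    w <- config$high_weight[id]
    if (is.na(w)) w <- config$high_weight_default
    hi <- stats::runif(k) < w
    p_abx <- ifelse(hi,
                    stats::rbeta(k, config$p_abx_high[1], config$p_abx_high[2]),
                    stats::rbeta(k, config$p_abx_low[1], config$p_abx_low[2]))
    pieces[[i]] <- data.frame(
      code = sample(pool, k), chapter_id = id, p_abx = p_abx,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  n <- nrow(out)
  out$description <- paste("synthetic condition", out$code)
  out$is_covid <- FALSE
  if (config$n_covid > 0L) {
    resp <- which(out$chapter_id %in% c("infectious", "respiratory"))
    out$is_covid[sample(resp, min(config$n_covid, length(resp)))] <- TRUE
  }
  out$contested <- stats::runif(n) < config$controversy_fraction
  out$contested_endorse <- stats::runif(n) < config$contested_endorse_prob
  out[, c("code", "description", "chapter_id", "is_covid", "p_abx",
          "contested", "contested_endorse")]
}

#' Simulate the dual review with adjudication
#'
#' Each of two reviewers classifies a code for inclusion iff its latent
#' `p_abx` meets the proposal threshold (boundary included), flipping
#' independently with the configured error rate; discordant pairs receive
#' an error-free third review. Output satisfies the adjudication
#' invariants of [adjudicate()].
#'
#' @param latents Output of [simulate_codes()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A proposal data.frame (`code`, `reviewer1`, `reviewer2`,
#'   `reviewer3`, `final_proposal`, `adjudicated`).
#' @export
simulate_reviewers <- function(latents, config = sim_config(), seed = 1L) {
  stopifnot(is.data.frame(latents), all(c("code", "p_abx") %in% names(latents)))
  set.seed(seed)
  n <- nrow(latents)
  truth <- ifelse(latents$p_abx >= config$proposal_threshold,
                  "include", "exclude")
  flip <- function(x) ifelse(x == "include", "exclude", "include")
  e <- config$reviewer_error_rate
  r1 <- ifelse(stats::runif(n) < e, flip(truth), truth)
  r2 <- ifelse(stats::runif(n) < e, flip(truth), truth)
  r3 <- ifelse(r1 != r2, truth, NA_character_)
  cbind(data.frame(code = latents$code, stringsAsFactors = FALSE),
        adjudicate(r1, r2, r3))
}

#' Panelist profiles
#'
#' @param config A [sim_config()]; `concordance` and `severity_shift`
#'   are recycled over the `n_panelists` panelists.
#' @return A data.frame `panelist`, `concordance`, `severity_shift`.
#' @export
panel_profiles <- function(config = sim_config()) {
  data.frame(
    panelist = sprintf("P%02d", seq_len(config$n_panelists)),
    concordance = rep_len(config$concordance, config$n_panelists),
    severity_shift = rep_len(config$severity_shift, config$n_panelists),
    stringsAsFactors = FALSE
  )
}

#' Simulate one round of panel votes
#'
#' Round 1: panelists endorse a correct proposal (scores from the
#' endorse distribution, mass on 7..9) with their profile's concordance
#' and reject an incorrect one (mass on 1..3); contested codes draw from
#' the contested distribution so the agreement rule fails with high
#' probability. Rounds 2 and later: each drawn score is contracted toward
#' the code's majority-side consensus target (8 when the panel converges
#' to endorse, 2 to reject) by factor `(1 - convergence)^(round - 1)`,
#' reproducing the full-consensus second round. Per-panelist
#' `severity_shift` is added before contraction; all scores are clipped
#' to 1..9.
#'
#' @param proposals Proposal data.frame (see [simulate_reviewers()]).
#' @param latents Output of [simulate_codes()].
#' @param profiles Output of [panel_profiles()]; must have
#'   `config$n_panelists` rows.
#' @param round_number Round to simulate (1-based).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param pending Codes to vote on this round (default: all proposed).
#' @return A vote data.frame `round,code,panelist,score`.
#' @export
simulate_votes <- function(proposals, latents, profiles = panel_profiles(config),
                           round_number = 1L, config = sim_config(),
                           seed = 1L, pending = NULL) {
  stopifnot(is.data.frame(proposals), is.data.frame(latents))
  if (nrow(profiles) != config$n_panelists) {
    stop("profiles must have exactly n_panelists = ", config$n_panelists, " rows")
  }
  if (is.null(pending)) pending <- proposals$code
  set.seed(seed)
  idx <- match(pending, latents$code)
  pidx <- match(pending, proposals$code)
  if (anyNA(idx) || anyNA(pidx)) {
    stop("pending codes missing from latents or proposals")
  }
  nc <- length(pending)
  np <- nrow(profiles)
  truth <- latents$p_abx[idx] >= config$proposal_threshold
  correct <- (proposals$final_proposal[pidx] == "include") == truth
  contested <- latents$contested[idx]
  # endorse target side per code (used for contested draws' convergence
  # and for later-round contraction)
  target_high <- ifelse(contested, latents$contested_endorse[idx], correct)

  # matrices nc x np
  u <- matrix(stats::runif(nc * np), nc, np)
  conc <- matrix(rep(profiles$concordance, each = nc), nc, np)
  endorse <- ifelse(matrix(correct, nc, np), u < conc, u >= conc)
  draw_pool <- function(dist, k) sample.int(9L, k, replace = TRUE, prob = dist)
  score <- matrix(0L, nc, np)
  cmask <- matrix(contested, nc, np)
  emask <- !cmask & endorse
  rmask <- !cmask & !endorse
  score[cmask] <- draw_pool(config$score_contested, sum(cmask))
  score[emask] <- draw_pool(config$score_endorse, sum(emask))
  score[rmask] <- draw_pool(config$score_reject, sum(rmask))
  score <- score + matrix(rep(profiles$severity_shift, each = nc), nc, np)
  if (round_number > 1L) {
    target <- matrix(ifelse(target_high, 8, 2), nc, np)
    fac <- (1 - config$convergence)^(round_number - 1L)
    score <- floor(target + fac * (score - target) + 0.5)
  }
  score <- pmin(9L, pmax(1L, score))
  data.frame(
    round = as.integer(round_number),
    code = rep(pending, times = np),
    panelist = rep(profiles$panelist, each = nc),
    score = as.integer(score),
    stringsAsFactors = FALSE
  )
}

#' A vote source backed by the simulator
#'
#' Wraps [simulate_votes()] as the vote-source function [run_delphi()]
#' expects; round `r` uses seed `seed + r` so the full run is
#' reproducible from one seed.
#'
#' @inheritParams simulate_votes
#' @param seed Base integer seed (keep below 2^31 - max_rounds).
#' @return A function `(round_number, pending) -> votes`.
#' @export
simulated_vote_source <- function(proposals, latents,
                                  profiles = panel_profiles(config),
                                  config = sim_config(), seed = 1L) {
  force(proposals); force(latents); force(profiles); force(config); force(seed)
  function(round_number, pending) {
    simulate_votes(proposals, latents, profiles,
                   round_number = round_number, config = config,
                   seed = seed + round_number, pending = pending)
  }
}

#' Simulate a full consensus study end to end
#'
#' Convenience wrapper: code universe, dual review, and the multi-round
#' Delphi run, all from one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param delphi A [delphi_config()].
#' @return A list: `codes` (latents), `proposals`, `outcome`
#'   (a `consensus_outcome`), `config`.
#' @export
simulate_delphi_study <- function(config = sim_config(), seed = 1L,
                                  delphi = delphi_config()) {
  codes <- simulate_codes(config, seed = seed)
  proposals <- simulate_reviewers(codes, config, seed = seed + 500000L)
  profiles <- panel_profiles(config)
  src <- simulated_vote_source(proposals, codes, profiles, config,
                               seed = seed + 1000000L)
  outcome <- run_delphi(proposals, src, config = delphi)
  list(codes = codes, proposals = proposals, outcome = outcome,
       config = config)
}
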