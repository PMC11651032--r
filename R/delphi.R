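# Multi-round consensus engine: proposals in, rounds of panel votes
# iterated until every code reaches agreement (or a round cap), final
# include/exclude classification out.

#' Engine configuration
#'
#' @param agreement An [agreement_config()].
#' @param low_agreement What a low-side agreement (panel rejects the
#'   proposal) does to the final classification: `"overturn"` (default,
#'   the proposal flips — the panel scored the *proposed classification*,
#'   so firm rejection endorses its opposite) or `"reclassify_exclude"`
#'   (rejected proposals fall back to exclusion regardless of direction).
#' @param max_rounds Hard cap on rounds; codes still contested when it is
#'   reached are reported as unresolved, never silently classified.
#' @param mode Completeness handling for vote tables, `"strict"` or
#'   `"permissive"` (see [validate_votes()]).
#' @return A list of class `delphi_config`.
#' @export
delphi_config <- function(agreement = agreement_config(),
                          low_agreement = c("overturn", "reclassify_exclude"),
                          max_rounds = 10L,
                          mode = c("strict", "permissive")) {
  structure(
    list(agreement = agreement,
         low_agreement = match.arg(low_agreement),
         max_rounds = as.integer(max_rounds),
         mode = match.arg(mode)),
    class = "delphi_config"
  )
}

#' Resolve the final classification from proposal and agreement
#'
#' Panelists score their agreement with the *proposed* classification, so
#' agreement polarity composes with the proposal: high-side agreement
#' means the proposal stands; low-side agreement means the panel firmly
#' rejects it, which under the default endorsement semantics overturns it
#' (include becomes exclude and vice versa).
#'
#' @param proposal Character vector, `"include"`/`"exclude"`.
#' @param status Character vector of agreement statuses
#'   (`"AGREE_HIGH"`/`"AGREE_LOW"`); `"NO_AGREEMENT"` is rejected.
#' @param config A [delphi_config()].
#' @return Character vector of final classifications.
#' @export
resolve_direction <- function(proposal, status, config = delphi_config()) {
  proposal <- .check_classification(proposal, "proposal")
  if (any(!status %in% c("AGREE_HIGH", "AGREE_LOW"))) {
    stop("direction is only defined for agreed codes (AGREE_HIGH/AGREE_LOW)")
  }
  flipped <- if (config$low_agreement == "overturn") {
    ifelse(proposal == "include", "exclude", "include")
  } else {
    "exclude"
  }
  ifelse(status == "AGREE_HIGH", proposal, flipped)
}

#' Run a single voting round
#'
#' Classifies every pending code from that round's votes. Votes must
#' cover exactly the pending codes: votes for non-pending codes are
#' rejected; pending codes without votes are rejected in strict mode.
#'
#' @param pending Character vector of codes awaiting consensus.
#' @param votes Vote data.frame (`round,code,panelist,score`) for this
#'   round.
#' @param round_number Round the votes belong to.
#' @param config A [delphi_config()].
#' @param roster Optional [panel_roster()] for completeness checking.
#' @return A list of class `round_record`: `round_number`,
#'   `evaluated_codes`, `results` (data.frame, one row per code: median,
#'   q1, q3, iqr, ipras, status), `carried_forward`.
#' @export
run_round <- function(pending, votes, round_number = 1L,
                      config = delphi_config(), roster = NULL) {
  pending <- parse_icd9(pending)
  votes <- validate_votes(votes, roster = roster, mode = config$mode)
  votes <- votes[votes$round == round_number, , drop = FALSE]
  extra <- setdiff(unique(votes$code), pending)
  if (length(extra) > 0L) {
    stop("votes reference code(s) not pending in round ", round_number, ": ",
         paste(sQuote(extra[seq_len(min(5L, length(extra)))]), collapse = ", "))
  }
  absent <- setdiff(pending, unique(votes$code))
  if (length(absent) > 0L) {
    msg <- paste0("no round-", round_number, " votes for pending code(s): ",
                  paste(sQuote(absent[seq_len(min(5L, length(absent)))]),
                        collapse = ", "))
    if (config$mode == "strict") stop(msg) else warning(msg)
  }
  results <- .classify_many(votes$code, votes$score, config$agreement)
  structure(
    list(round_number = as.integer(round_number),
         evaluated_codes = results$code,
         results = results,
         carried_forward = results$code[results$status == "NO_AGREEMENT"]),
    class = "round_record"
  )
}

#' @export
print.round_record <- function(x, ...) {
  cat(sprintf("Round %d: %d codes evaluated, %d agreed, %d carried forward\n",
              x$round_number, length(x$evaluated_codes),
              length(x$evaluated_codes) - length(x$carried_forward),
              length(x$carried_forward)))
  invisible(x)
}

#' Turn per-round vote tables into a vote source
#'
#' The engine pulls each round's votes from a *vote source*: a function
#' `(round_number, pending_codes) -> vote data.frame`. This helper wraps
#' a list of in-memory tables or files, one per round in order.
#'
#' @param rounds A list of vote data.frames, or a character vector of
#'   vote-file paths, element `r` holding round `r`.
#' @return A vote-source function.
#' @export
vote_source_from_rounds <- function(rounds) {
  force(rounds)
  function(round_number, pending) {
    if (round_number > length(rounds)) {
      stop("no votes available for round ", round_number,
           " (", length(rounds), " round(s) supplied)")
    }
    r <- rounds[[round_number]]
    if (is.character(r)) r <- read_votes(r)
    r
  }
}

#' Run the full Delphi consensus procedure
#'
#' Iterates voting rounds from the adjudicated review proposals until
#' every code reaches agreement or `max_rounds` is exhausted. Round 1
#' evaluates every proposed code; each later round evaluates exactly the
#' codes carried forward from the previous one. No information is fed
#' back to the vote source beyond the pending-code list.
#'
#' @param proposals Proposal data.frame (see [read_proposals()] /
#'   [adjudicate()]): columns `code`, `final_proposal` at minimum.
#' @param vote_source Function `(round_number, pending) -> votes`
#'   (see [vote_source_from_rounds()]).
#' @param config A [delphi_config()].
#' @param roster Optional [panel_roster()] for completeness checks.
#' @return An object of class `consensus_outcome`: list with
#'   * `final` — data.frame `code, proposal, classification,
#'     settling_round, status` (classification `NA` for unresolved);
#'   * `history` — list of `round_record`s;
#'   * `rounds_used`, `complete` (logical), `unresolved` (codes).
#' @export
run_delphi <- function(proposals, vote_source, config = delphi_config(),
                       roster = NULL) {
  stopifnot(is.data.frame(proposals),
            all(c("code", "final_proposal") %in% names(proposals)),
            is.function(vote_source))
  codes <- parse_icd9(proposals$code)
  if (anyDuplicated(codes)) stop("duplicate codes in proposals")
  proposal <- .check_classification(proposals$final_proposal, "final_proposal")
  names(proposal) <- codes

  final_class <- stats::setNames(rep(NA_character_, length(codes)), codes)
  final_status <- stats::setNames(rep(NA_character_, length(codes)), codes)
  settling <- stats::setNames(rep(NA_integer_, length(codes)), codes)
  history <- list()
  pending <- codes
  r <- 0L
  while (length(pending) > 0L && r < config$max_rounds) {
    r <- r + 1L
    votes <- vote_source(r, pending)
    rec <- run_round(pending, votes, round_number = r, config = config,
                     roster = roster)
    history[[r]] <- rec
    agreed <- rec$results[rec$results$status != "NO_AGREEMENT", , drop = FALSE]
    if (nrow(agreed) > 0L) {
      final_class[agreed$code] <-
        resolve_direction(proposal[agreed$code], agreed$status, config)
      final_status[agreed$code] <- agreed$status
      settling[agreed$code] <- r
    }
    pending <- rec$carried_forward
  }
  unresolved <- pending
  final <- data.frame(
    code = codes,
    proposal = unname(proposal),
    classification = unname(final_class[codes]),
    settling_round = unname(settling[codes]),
    status = ifelse(is.na(final_class[codes]), "UNRESOLVED",
                    unname(final_status[codes])),
    stringsAsFactors = FALSE
  )
  structure(
    list(final = final, history = history, rounds_used = r,
         complete = length(unresolved) == 0L, unresolved = unresolved),
    class = "consensus_outcome"
  )
}

#' @export
print.consensus_outcome <- function(x, ...) {
  inc <- sum(x$final$classification == "include", na.rm = TRUE)
  exc <- sum(x$final$classification == "exclude", na.rm = TRUE)
  cat(sprintf(
    "Delphi consensus outcome: %d codes, %d round(s)\n  included %d, excluded %d, unresolved %d%s\n",
    nrow(x$final), x$rounds_used, inc, exc, length(x$unresolved),
    if (x$complete) "" else "  [PARTIAL OUTCOME]"))
  invisible(x)
}

#' Write a consensus outcome to a directory
#'
#' Emits `final_classification.csv` (`code,classification,settling_round`),
#' one `round_<r>_results.csv` per round (code, median, q1, q3, iqr,
#' ipras, status), and `manifest.json` (config echo, counts, warnings).
#'
#' @param outcome A `consensus_outcome`.
#' @param dir Output directory (created if needed).
#' @param config The [delphi_config()] used (echoed into the manifest).
#' @return `dir`, invisibly.
#' @export
write_outcome <- function(outcome, dir, config = delphi_config()) {
  stopifnot(inherits(outcome, "consensus_outcome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    outcome$final[, c("code", "classification", "settling_round")],
    file.path(dir, "final_classification.csv"), row.names = FALSE, na = "")
  for (rec in outcome$history) {
    utils::write.csv(
      rec$results,
      file.path(dir, sprintf("round_%d_results.csv", rec$round_number)),
      row.names = FALSE)
  }
  manifest <- list(
    total_codes = nrow(outcome$final),
    rounds_used = outcome$rounds_used,
    complete = outcome$complete,
    included = sum(outcome$final$classification == "include", na.rm = TRUE),
    excluded = sum(outcome$final$classification == "exclude", na.rm = TRUE),
    unresolved = outcome$unresolved,
    config = config[c("low_agreement", "max_rounds", "mode")],
    agreement = unclass(config$agreement)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
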