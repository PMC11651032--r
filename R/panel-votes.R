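# Reviewer proposals and per-round panel Likert votes: data model + file I/O.
# Classifications are serialized as "include"/"exclude"; scores are integers
# on the 9-point Likert scale (1 = totally disagree, 9 = totally agree).

.classifications <- c("include", "exclude")

.check_classification <- function(x, what) {
  x <- tolower(as.character(x))
  bad <- !is.na(x) & !(x %in% .classifications)
  if (any(bad)) {
    stop(what, " must be 'include' or 'exclude', got ",
         paste(sQuote(unique(x[bad])), collapse = ", "))
  }
  x
}

#' Adjudicate a dual-review classification
#'
#' Two reviewers independently classify each code; a third reviewer
#' resolves discrepant classifications. A concordant pair stands as the
#' final proposal (no third review allowed); a discordant pair requires a
#' third review whose classification becomes final.
#'
#' @param reviewer1,reviewer2 Character vectors of `"include"`/`"exclude"`.
#' @param reviewer3 Optional third-review classification; must be `NA`
#'   where the first two reviewers agree and present where they differ.
#' @return A data.frame with columns `reviewer1`, `reviewer2`, `reviewer3`,
#'   `final_proposal`, `adjudicated`.
#' @examples
#' adjudicate("include", "exclude", "exclude")
#' @export
adjudicate <- function(reviewer1, reviewer2, reviewer3 = NA_character_) {
  r1 <- .check_classification(reviewer1, "reviewer1")
  r2 <- .check_classification(reviewer2, "reviewer2")
  r3 <- .check_classification(reviewer3, "reviewer3")
  n <- max(length(r1), length(r2), length(r3))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); r3 <- rep_len(r3, n)
  if (anyNA(r1) || anyNA(r2)) stop("reviewer1 and reviewer2 are required")
  discordant <- r1 != r2
  if (any(discordant & is.na(r3))) {
    stop("adjudication required: reviewers disagree and no third review given")
  }
  if (any(!discordant & !is.na(r3))) {
    stop("third review supplied for concordant pair(s); adjudication applies only to discrepant classifications")
  }
  data.frame(
    reviewer1 = r1, reviewer2 = r2, reviewer3 = r3,
    final_proposal = ifelse(discordant, r3, r1),
    adjudicated = discordant,
    stringsAsFactors = FALSE
  )
}

#' Read a reviewer-proposal file
#'
#' Delimited text with header `code,reviewer1,reviewer2,reviewer3,final_proposal`
#' (`reviewer3` blank when unused). The adjudication invariants are
#' re-derived and checked against the stored `final_proposal`.
#'
#' @param file Path to the proposal file.
#' @return A data.frame with columns `code`, `reviewer1`, `reviewer2`,
#'   `reviewer3`, `final_proposal`, `adjudicated`.
#' @export
read_proposals <- function(file) {
  df <- utils::read.csv(file, colClasses = "character", na.strings = c("", "NA"))
  needed <- c("code", "reviewer1", "reviewer2", "reviewer3", "final_proposal")
  if (!all(needed %in% names(df))) {
    stop("proposal file must have columns ", paste(needed, collapse = ", "))
  }
  code <- parse_icd9(df$code)
  if (anyDuplicated(code)) {
    stop("duplicate code(s) in proposal file: ",
         paste(sQuote(unique(code[duplicated(code)])), collapse = ", "))
  }
  adj <- adjudicate(df$reviewer1, df$reviewer2, df$reviewer3)
  stored <- .check_classification(df$final_proposal, "final_proposal")
  if (any(stored != adj$final_proposal)) {
    stop("stored final_proposal contradicts the adjudication rule at code(s): ",
         paste(sQuote(code[stored != adj$final_proposal]), collapse = ", "))
  }
  cbind(data.frame(code = code, stringsAsFactors = FALSE), adj)
}

#' Write a reviewer-proposal file
#'
#' @param proposals Data.frame as returned by [read_proposals()] or built
#'   from [adjudicate()] plus a `code` column.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_proposals <- function(proposals, file) {
  needed <- c("code", "reviewer1", "reviewer2", "reviewer3", "final_proposal")
  stopifnot(all(needed %in% names(proposals)))
  out <- proposals[order(proposals$code), needed, drop = FALSE]
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Construct a panel roster
#'
#' Panelist identity is an opaque string (one vote per participating
#' unit); the study-replication roster has 18 panelists.
#'
#' @param ids Character vector of unique panelist identifiers.
#' @return A character vector of class `panel_roster`.
#' @export
panel_roster <- function(ids = sprintf("P%02d", 1:18)) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("panelist ids must be unique")
  if (length(ids) == 0L) stop("roster must contain at least one panelist")
  structure(ids, class = "panel_roster")
}

.check_votes_frame <- function(votes) {
  needed <- c("round", "code", "panelist", "score")
  if (!all(needed %in% names(votes))) {
    stop("vote data must have columns ", paste(needed, collapse = ", "))
  }
  votes
}

#' Read a per-round vote file
#'
#' Delimited text with header `round,code,panelist,score`, one row per
#' (round, code, panelist) vote. Scores must be integers in 1..9; out of
#' range or non-integer scores and duplicate votes are rejected with the
#' offending row named. If a roster is supplied, completeness is checked
#' against it: in `strict` mode missing (round, code, panelist) triples
#' are an error, in `permissive` mode a warning — surfacing, never
#' imputing, the follow-up the study performed to reach completeness.
#'
#' @param file Path to the vote file.
#' @param roster Optional [panel_roster()] to check completeness against.
#' @param mode `"strict"` (default) or `"permissive"`.
#' @return A data.frame with columns `round` (integer), `code`,
#'   `panelist`, `score` (integer). An attribute `"missing"` carries the
#'   completeness report (data.frame of absent triples).
#' @export
read_votes <- function(file, roster = NULL, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(file, colClasses = "character")
  .check_votes_frame(df)
  validate_votes(
    data.frame(round = df$round, code = df$code, panelist = df$panelist,
               score = df$score, stringsAsFactors = FALSE),
    roster = roster, mode = mode
  )
}

#' Validate an in-memory vote table
#'
#' The same checks [read_votes()] applies after parsing: Likert bounds,
#' integer scores, duplicate votes, and (optionally) roster completeness.
#'
#' @inheritParams read_votes
#' @param votes Data.frame with columns `round,code,panelist,score`.
#' @return The validated data.frame with typed columns and a `"missing"`
#'   attribute (see [read_votes()]).
#' @export
validate_votes <- function(votes, roster = NULL,
                           mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  .check_votes_frame(votes)
  if (nrow(votes) == 0L) {
    out <- data.frame(round = integer(), code = character(),
                      panelist = character(), score = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "missing") <- .missing_votes(out, NULL)
    return(out)
  }
  round <- suppressWarnings(as.numeric(votes$round))
  score <- suppressWarnings(as.numeric(votes$score))
  bad_round <- is.na(round) | round != as.integer(round) | round < 1
  if (any(bad_round)) {
    stop("invalid round number at row(s): ",
         paste(which(bad_round)[seq_len(min(5L, sum(bad_round)))], collapse = ", "))
  }
  bad_score <- is.na(score) | score != as.integer(score) | score < 1 | score > 9
  if (any(bad_score)) {
    stop("score outside the 1..9 Likert scale (or non-integer) at row(s): ",
         paste(which(bad_score)[seq_len(min(5L, sum(bad_score)))], collapse = ", "))
  }
  code <- parse_icd9(votes$code)
  panelist <- as.character(votes$panelist)
  key <- paste(round, code, panelist, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (round, code, panelist) vote at row(s): ",
         paste(which(duplicated(key))[seq_len(min(5L, sum(duplicated(key))))],
               collapse = ", "))
  }
  out <- data.frame(round = as.integer(round), code = code,
                    panelist = panelist, score = as.integer(score),
                    stringsAsFactors = FALSE)
  missing <- .missing_votes(out, roster)
  if (nrow(missing) > 0L) {
    msg <- sprintf(
      "%d missing vote(s) relative to the roster, e.g. round %s code %s panelist %s",
      nrow(missing), missing$round[1L], missing$code[1L], missing$panelist[1L])
    if (mode == "strict") stop(msg) else warning(msg)
  }
  attr(out, "missing") <- missing
  out
}

.missing_votes <- function(votes, roster) {
  empty <- data.frame(round = integer(), code = character(),
                      panelist = character(), stringsAsFactors = FALSE)
  if (is.null(roster)) return(empty)
  combos <- unique(votes[, c("round", "code")])
  full <- merge(combos, data.frame(panelist = as.character(roster),
                                   stringsAsFactors = FALSE))
  have <- paste(votes$round, votes$code, votes$panelist, sep = "\r")
  want <- paste(full$round, full$code, full$panelist, sep = "\r")
  miss <- full[!(want %in% have), c("round", "code", "panelist"), drop = FALSE]
  miss <- miss[order(miss$round, miss$code, miss$panelist), , drop = FALSE]
  rownames(miss) <- NULL
  miss
}

#' Write a per-round vote file
#'
#' Deterministic serialization: rows sorted by (round, code, panelist) so
#' that `read_votes(write_votes(v))` reproduces `v` up to that ordering.
#'
#' @param votes Validated vote data.frame (see [validate_votes()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_votes <- function(votes, file) {
  .check_votes_frame(votes)
  out <- votes[order(votes$round, votes$code, votes$panelist),
               c("round", "code", "panelist", "score"), drop = FALSE]
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Split a vote table into per-code vote sets
#'
#' @param votes Validated vote data.frame.
#' @param round Optional round number to restrict to.
#' @return A named list (by code) of integer score vectors, one per
#'   (round, code); list names are codes, each element carries its round
#'   as attribute `"round"` and panelists as names.
#' @export
vote_sets <- function(votes, round = NULL) {
  .check_votes_frame(votes)
  if (!is.null(round)) votes <- votes[votes$round == round, , drop = FALSE]
  split_scores <- split(seq_len(nrow(votes)), votes$code)
  lapply(split_scores, function(i) {
    s <- votes$score[i]
    names(s) <- votes$panelist[i]
    attr(s, "round") <- unique(votes$round[i])
    s
  })
}
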