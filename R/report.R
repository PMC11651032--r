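# Descriptive reporting: flow tallies, chapter breakdowns, percentages.
# Reports always carry counts and recompute percentages at print time;
# percentages are never stored or accepted as inputs, so arithmetic
# inconsistencies in source material cannot propagate.

#' Percentage with explicit rounding mode
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero (default)
#' or truncated toward zero, to `decimals` places. Half-away-from-zero is
#' the convention of most published tables; `trunc` is provided for
#' reproducing sources that truncate.
#'
#' @param numerator,denominator Non-negative count and positive count.
#' @param decimals Number of decimal places (default 1).
#' @param mode `"round"` (half away from zero) or `"truncate"`.
#' @return Numeric percentage.
#' @examples
#' percent(2967, 16229, 2)            # 18.28
#' percent(8, 17, 2, mode = "truncate") # 47.05
#' @export
percent <- function(numerator, denominator, decimals = 1L,
                    mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0)) stop("numerator must be non-negative")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  if (mode == "round") {
    sign(x) * floor(abs(x) * f + 0.5) / f
  } else {
    trunc(x * f) / f
  }
}

#' Flow summary of a consensus outcome
#'
#' The tallies of the study flow chart: codes evaluated, first-round
#' agreements split by direction, contested codes, final classification
#' counts, and rounds used.
#'
#' @param outcome A `consensus_outcome` (see [run_delphi()]).
#' @param strict If `TRUE` (default), unresolved codes are an error; if
#'   `FALSE` they are tallied separately.
#' @return A list of class `flow_summary` with fields `total_codes`,
#'   `round1_agreed`, `round1_included`, `round1_excluded`, `contested`,
#'   `final_included`, `final_excluded`, `unresolved`, `rounds_used`.
#' @export
flow_summary <- function(outcome, strict = TRUE) {
  stopifnot(inherits(outcome, "consensus_outcome"))
  if (strict && !outcome$complete) {
    stop("outcome has ", length(outcome$unresolved),
         " unresolved code(s); rerun with strict = FALSE to tally them")
  }
  fin <- outcome$final
  r1 <- fin$settling_round == 1L & !is.na(fin$settling_round)
  fs <- list(
    total_codes = nrow(fin),
    round1_agreed = sum(r1),
    round1_included = sum(r1 & fin$classification == "include"),
    round1_excluded = sum(r1 & fin$classification == "exclude"),
    contested = nrow(fin) - sum(r1),
    final_included = sum(fin$classification == "include", na.rm = TRUE),
    final_excluded = sum(fin$classification == "exclude", na.rm = TRUE),
    unresolved = sum(is.na(fin$classification)),
    rounds_used = outcome$rounds_used
  )
  structure(fs, class = "flow_summary")
}

#' Build and validate a flow summary from externally reported counts
#'
#' For study-replication work the tallies may come from a published flow
#' chart rather than a run. The additive invariants are checked; if a
#' stated universe size disagrees with the evaluated total the mismatch
#' is surfaced as a warning, never reconciled silently.
#'
#' @param round1_included,round1_excluded First-round agreement split.
#' @param contested Codes carried to later rounds.
#' @param final_included,final_excluded Final classification counts.
#' @param rounds_used Number of rounds.
#' @param stated_total Optional externally stated universe size to check
#'   `round1_agreed + contested` against.
#' @return A `flow_summary`.
#' @export
flow_from_counts <- function(round1_included, round1_excluded, contested,
                             final_included, final_excluded,
                             rounds_used = 2L, stated_total = NULL) {
  round1_agreed <- round1_included + round1_excluded
  total <- round1_agreed + contested
  if (final_included + final_excluded != total) {
    stop("final classification counts (", final_included + final_excluded,
         ") do not sum to the evaluated total (", total, ")")
  }
  if (final_included < round1_included || final_excluded < round1_excluded) {
    stop("final counts cannot be smaller than first-round counts")
  }
  if (!is.null(stated_total) && stated_total != total) {
    warning("stated universe size (", stated_total,
            ") differs from evaluated codes (", total, ")")
  }
  structure(
    list(total_codes = total, round1_agreed = round1_agreed,
         round1_included = round1_included, round1_excluded = round1_excluded,
         contested = contested, final_included = final_included,
         final_excluded = final_excluded, unresolved = 0L,
         rounds_used = rounds_used),
    class = "flow_summary"
  )
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Consensus flow: %d codes evaluated over %d round(s)\n",
           "  round 1: %d agreed (%d include / %d exclude), %d contested\n",
           "  final:   %d included (%.1f%%), %d excluded%s\n"),
    x$total_codes, x$rounds_used,
    x$round1_agreed, x$round1_included, x$round1_excluded, x$contested,
    x$final_included, percent(x$final_included, x$total_codes, 1L),
    x$final_excluded,
    if (x$unresolved > 0) sprintf(", %d unresolved", x$unresolved) else ""))
  invisible(x)
}

#' Chapter breakdown of a code subset
#'
#' Counts (and percentages of the subset) per ICD-9-CM chapter, e.g. for
#' the final inclusion set or the contested codes. Percentages are
#' recomputed from counts via [percent()].
#'
#' @param codes Character vector of normalized codes (non-empty).
#' @param chapters Chapter table (see [icd9_chapters()]).
#' @param decimals Decimal places for the percentage column (default 1).
#' @param label Subset label carried as attribute `"label"`.
#' @return A data.frame `chapter_id, name, count, percent`, sorted by
#'   descending count; counts sum to `length(codes)`.
#' @export
chapter_breakdown <- function(codes, chapters = icd9_chapters(),
                              decimals = 1L, label = "subset") {
  if (length(codes) == 0L) stop("empty code subset: no denominator")
  ch <- assign_chapter(parse_icd9(codes), chapters)
  counts <- table(factor(ch, levels = chapters$chapter_id))
  out <- data.frame(
    chapter_id = chapters$chapter_id,
    name = chapters$name,
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out$percent <- percent(out$count, length(codes), decimals)
  out <- out[order(-out$count, out$chapter_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  out
}

#' Write report files for a consensus outcome
#'
#' Emits `flow_summary.json`, `chapter_breakdown_included.csv`,
#' `chapter_breakdown_contested.csv` (when any code needed more than one
#' round), and a plain-text `summary.txt` mirroring the flow narrative.
#'
#' @param outcome A `consensus_outcome`.
#' @param chapters Chapter table.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(outcome, dir, chapters = icd9_chapters()) {
  stopifnot(inherits(outcome, "consensus_outcome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- flow_summary(outcome, strict = FALSE)
  jsonlite::write_json(unclass(fs), file.path(dir, "flow_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  fin <- outcome$final
  included <- fin$code[fin$classification == "include" & !is.na(fin$classification)]
  if (length(included) > 0L) {
    utils::write.csv(chapter_breakdown(included, chapters, label = "included"),
                     file.path(dir, "chapter_breakdown_included.csv"),
                     row.names = FALSE)
  }
  contested <- fin$code[is.na(fin$settling_round) | fin$settling_round > 1L]
  if (length(contested) > 0L) {
    utils::write.csv(chapter_breakdown(contested, chapters, label = "contested"),
                     file.path(dir, "chapter_breakdown_contested.csv"),
                     row.names = FALSE)
  }
  txt <- utils::capture.output(print(fs))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
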