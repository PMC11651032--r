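#' @keywords internal
"_PACKAGE"

# Syntactic families of ICD-9-CM identifiers. Codes are opaque leaves:
# no hierarchy expansion (008 does not imply 008.x), each code stands alone.
.icd9_patterns <- c(
  numeric = "^[0-9]{3}(\\.[0-9]{1,2})?$",
  V       = "^V[0-9]{2}(\\.[0-9]{1,2})?$",
  E       = "^E[0-9]{3}(\\.[0-9])?$"
)

#' Parse and normalize ICD-9-CM code identifiers
#'
#' Trims whitespace, upper-cases the V/E prefix, and validates the
#' identifier against the three syntactic families of ICD-9-CM:
#' numeric (`001`--`999`, up to two decimals), V-codes (`Vnn`, up to two
#' decimals) and E-codes (`Ennn`, one decimal).
#'
#' @param raw Character vector of raw code identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' parse_icd9(c("008.45", " v09.0 ", "E950.1"))
#' @export
parse_icd9 <- function(raw) {
  if (length(raw) == 0L) stop("no code identifiers supplied")
  if (!is.character(raw)) raw <- as.character(raw)
  norm <- toupper(trimws(raw))
  bad <- is.na(norm) | !nzchar(norm) | is.na(icd9_family(norm))
  if (any(bad)) {
    stop(
      "malformed ICD-9-CM identifier(s): ",
      paste(sQuote(raw[bad][seq_len(min(5L, sum(bad)))]), collapse = ", "),
      if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L),
      "; expected numeric 'nnn[.nn]', V-code 'Vnn[.nn]' or E-code 'Ennn[.n]'"
    )
  }
  norm
}

#' Syntactic family of an ICD-9-CM identifier
#'
#' @param code Character vector of (possibly unnormalized) identifiers.
#' @return Character vector with values `"numeric"`, `"V"`, `"E"`, or `NA`
#'   for identifiers matching no family.
#' @export
icd9_family <- function(code) {
  fam <- rep(NA_character_, length(code))
  for (f in names(.icd9_patterns)) {
    fam[is.na(fam) & grepl(.icd9_patterns[[f]], code)] <- f
  }
  fam
}

#' Is a code part of the supplementary classification?
#'
#' V- and E-prefixed codes form the two supplementary classifications of
#' ICD-9-CM (health-status factors and external causes).
#'
#' @param code Character vector of normalized identifiers.
#' @return Logical vector.
#' @export
is_supplementary <- function(code) {
  icd9_family(code) %in% c("V", "E")
}

#' Chapter table of ICD-9-CM
#'
#' The 17 numeric chapters plus the two supplementary classifications,
#' shipped as data (a bundled delimited table) rather than hard-coded, so
#' the ranges can be corrected without touching logic.
#'
#' @param file Optional path to an alternative chapter table with columns
#'   `chapter_id,name,prefix_start,prefix_end,family`.
#' @return A data.frame with one row per chapter.
#' @export
icd9_chapters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "icd9_chapters.csv",
                        package = "delphicodes", mustWork = TRUE)
  }
  ch <- utils::read.csv(file, colClasses = "character")
  needed <- c("chapter_id", "name", "prefix_start", "prefix_end", "family")
  if (!all(needed %in% names(ch))) {
    stop("chapter table must have columns ", paste(needed, collapse = ", "))
  }
  num <- ch$family == "numeric"
  starts <- as.integer(ch$prefix_start[num])
  ends <- as.integer(ch$prefix_end[num])
  o <- order(starts)
  if (any(starts > ends) ||
      any(starts[o][-1] <= ends[o][-length(ends)])) {
    stop("numeric chapter prefix ranges must be disjoint, ordered intervals")
  }
  ch
}

#' Assign ICD-9-CM codes to chapters
#'
#' Maps each code to the unique chapter whose prefix interval contains its
#' three-character prefix. The decimal extension never changes the chapter
#' (`008` and `008.45` map identically).
#'
#' @param code Character vector of normalized identifiers (see
#'   [parse_icd9()]).
#' @param chapters Chapter table, as returned by [icd9_chapters()].
#' @return Character vector of `chapter_id` values.
#' @examples
#' assign_chapter(c("008.45", "941.20", "V01.79"))
#' @export
assign_chapter <- function(code, chapters = icd9_chapters()) {
  fam <- icd9_family(code)
  if (anyNA(fam)) {
    stop("unparseable code(s): ",
         paste(sQuote(code[is.na(fam)][seq_len(min(5L, sum(is.na(fam))))]),
               collapse = ", "))
  }
  out <- rep(NA_character_, length(code))
  for (f in c("V", "E")) {
    row <- chapters[chapters$family == f, , drop = FALSE]
    if (nrow(row) == 1L) out[fam == f] <- row$chapter_id
  }
  num <- fam == "numeric"
  if (any(num)) {
    prefix <- as.integer(substr(code[num], 1L, 3L))
    cnum <- chapters[chapters$family == "numeric", , drop = FALSE]
    cnum <- cnum[order(as.integer(cnum$prefix_start)), , drop = FALSE]
    idx <- findInterval(prefix, as.integer(cnum$prefix_start))
    ok <- idx >= 1L & prefix <= as.integer(cnum$prefix_end)[pmax(idx, 1L)]
    hit <- rep(NA_character_, length(prefix))
    hit[ok] <- cnum$chapter_id[idx[ok]]
    out[num] <- hit
  }
  if (anyNA(out)) {
    stop("code prefix outside all chapter ranges: ",
         paste(sQuote(unique(code[is.na(out)])), collapse = ", "))
  }
  out
}

#' Read a code-list file
#'
#' Reads a delimited code list (comma or tab, auto-detected from the
#' header line) with columns `code,description[,is_covid]`. Codes are
#' normalized with [parse_icd9()] and chapter-checked. The SARS-CoV-2
#' flag is carried as metadata from the file, never inferred.
#'
#' @param file Path to the code-list file.
#' @param chapters Chapter table used for validation.
#' @return A data.frame with columns `code`, `description`, `is_covid`,
#'   `chapter_id`, `is_supplementary`.
#' @export
read_code_list <- function(file, chapters = icd9_chapters()) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!all(c("code", "description") %in% names(df))) {
    stop("code list must have columns 'code' and 'description'")
  }
  code <- parse_icd9(df$code)
  if (anyDuplicated(code)) {
    stop("duplicate code(s) in code list: ",
         paste(sQuote(unique(code[duplicated(code)])), collapse = ", "))
  }
  is_covid <- if ("is_covid" %in% names(df)) {
    tolower(df$is_covid) %in% c("true", "t", "1", "yes")
  } else rep(FALSE, nrow(df))
  data.frame(
    code = code,
    description = df$description,
    is_covid = is_covid,
    chapter_id = assign_chapter(code, chapters),
    is_supplementary = is_supplementary(code),
    stringsAsFactors = FALSE
  )
}

#' Write a code-list file
#'
#' Inverse of [read_code_list()]: emits `code,description,is_covid` as
#' comma-separated text, sorted by code.
#'
#' @param codes Data.frame with at least `code` and `description` columns.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_code_list <- function(codes, file) {
  stopifnot(is.data.frame(codes), all(c("code", "description") %in% names(codes)))
  out <- data.frame(
    code = parse_icd9(codes$code),
    description = codes$description,
    is_covid = if ("is_covid" %in% names(codes)) codes$is_covid else FALSE,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$code), , drop = FALSE]
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}
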