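# Per-code agreement statistic for one voting round: median, quartiles,
# IQR, and the RAND/UCLA inter-percentile range adjusted for symmetry
# (IPRAS). A panel disagrees when the median falls in the uncertain band,
# or when a high median hides more spread than IPRAS tolerates.

#' Agreement-rule configuration
#'
#' All constants of the agreement rule live in configuration, not code.
#' Defaults: quartiles at probabilities 0.25/0.75 with the linear
#' interpolation convention (fractional rank `1 + (n-1)p`); IPRAS
#' `2.35 + 1.5 * |5 - (q1+q3)/2|` (base, slope, and scale midpoint from
#' the RAND/UCLA appropriateness methodology); median bands at 4 and 7.
#'
#' @param quantile_lo,quantile_hi Probabilities of the lower/upper
#'   quartile (defaults 0.25, 0.75).
#' @param quantile_method `"linear"` (interpolated, default) or
#'   `"nearest"` (order statistic at rank `floor(h + 0.5)`).
#' @param ipras_base,ipras_slope,ipras_center IPRAS constants (2.35, 1.5,
#'   and the 9-point scale midpoint 5).
#' @param median_low_cut,median_high_cut Median band edges: medians below
#'   `median_low_cut` signal low-side agreement, medians in
#'   `[median_low_cut, median_high_cut)` signal non-agreement, medians at
#'   or above `median_high_cut` signal high-side agreement subject to the
#'   IPRAS dispersion check.
#' @param symmetric_low_rule If `TRUE`, low medians are also subjected to
#'   the IPRAS dispersion check (off by default: the enumerated
#'   non-agreement rules cover only the middle band and the high band).
#' @return A list of class `agreement_config`.
#' @export
agreement_config <- function(quantile_lo = 0.25, quantile_hi = 0.75,
                             quantile_method = c("linear", "nearest"),
                             ipras_base = 2.35, ipras_slope = 1.5,
                             ipras_center = 5,
                             median_low_cut = 4, median_high_cut = 7,
                             symmetric_low_rule = FALSE) {
  quantile_method <- match.arg(quantile_method)
  stopifnot(quantile_lo >= 0, quantile_hi <= 1, quantile_lo <= quantile_hi,
            ipras_base >= 0, ipras_slope >= 0,
            median_low_cut <= median_high_cut)
  structure(
    list(quantile_lo = quantile_lo, quantile_hi = quantile_hi,
         quantile_method = quantile_method,
         ipras_base = ipras_base, ipras_slope = ipras_slope,
         ipras_center = ipras_center,
         median_low_cut = median_low_cut, median_high_cut = median_high_cut,
         symmetric_low_rule = isTRUE(symmetric_low_rule)),
    class = "agreement_config"
  )
}

#' Read an agreement configuration from a YAML or key=value file
#'
#' @param file Path to a YAML file (requires the yaml package) or a flat
#'   `key = value` text file.
#' @return An `agreement_config`.
#' @export
read_agreement_config <- function(file) {
  vals <- if (grepl("\\.ya?ml$", file) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(file)
  } else {
    lines <- grep("=", readLines(file), fixed = TRUE, value = TRUE)
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(p) {
      v <- trimws(p[2L])
      if (v %in% c("true", "false")) v == "true"
      else if (!is.na(suppressWarnings(as.numeric(v)))) as.numeric(v)
      else v
    })
    names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
    vals
  }
  known <- names(formals(agreement_config))
  do.call(agreement_config, vals[intersect(names(vals), known)])
}

# Order statistic x_(k) of integer scores via counts; scores in 1..9.
.order_stat <- function(counts, k) {
  min(which(cumsum(counts) >= k))
}

.quantile_counts <- function(counts, p, method) {
  n <- sum(counts)
  h <- 1 + (n - 1) * p
  if (method == "nearest") {
    return(.order_stat(counts, min(n, max(1, floor(h + 0.5)))))
  }
  lo <- floor(h)
  g <- h - lo
  x_lo <- .order_stat(counts, lo)
  if (g == 0) return(x_lo)
  x_hi <- .order_stat(counts, lo + 1)
  (1 - g) * x_lo + g * x_hi
}

#' Quartiles of a panel's Likert scores
#'
#' Computes (q1, median, q3) of a multiset of integer scores in 1..9.
#' The default convention places the p-quantile at fractional rank
#' `1 + (n-1)p` with linear interpolation between adjacent order
#' statistics; `"nearest"` takes the order statistic at the rounded rank.
#'
#' @param scores Integer vector of scores in 1..9 (non-empty).
#' @param config An [agreement_config()].
#' @return Named numeric vector `c(q1, median, q3)`.
#' @examples
#' score_quartiles(c(rep(7, 9), rep(8, 9)))
#' @export
score_quartiles <- function(scores, config = agreement_config()) {
  scores <- .check_scores(scores)
  counts <- tabulate(scores, nbins = 9L)
  c(q1 = .quantile_counts(counts, config$quantile_lo, config$quantile_method),
    median = .quantile_counts(counts, 0.5, config$quantile_method),
    q3 = .quantile_counts(counts, config$quantile_hi, config$quantile_method))
}

.check_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty score set")
  if (anyNA(scores) || any(scores != as.integer(scores)) ||
      any(scores < 1) || any(scores > 9)) {
    stop("scores must be integers on the 1..9 Likert scale")
  }
  as.integer(scores)
}

#' Inter-percentile range adjusted for symmetry (IPRAS)
#'
#' The RAND/UCLA disagreement threshold: a baseline spread tolerance that
#' grows as the inter-percentile midpoint departs from the scale
#' midpoint. With the default constants,
#' `ipras = 2.35 + 1.5 * |5 - (q1 + q3)/2|`, so it attains its lower
#' bound 2.35 exactly when the quartiles are centred on 5.
#'
#' @param q1,q3 Lower and upper quartiles, `1 <= q1 <= q3 <= 9`.
#' @param config An [agreement_config()].
#' @return Numeric IPRAS value.
#' @examples
#' ipras(3, 7)  # symmetric: 2.35
#' ipras(9, 9)  # asymmetry 4: 8.35
#' @export
ipras <- function(q1, q3, config = agreement_config()) {
  if (any(q1 > q3)) stop("q1 must not exceed q3")
  if (any(q1 < 1) || any(q3 > 9)) stop("quartiles must lie on the 1..9 scale")
  config$ipras_base +
    config$ipras_slope * abs(config$ipras_center - (q1 + q3) / 2)
}

#' Classify one code's round of votes
#'
#' Applies the tripartite agreement rule to a vote set:
#' * median below the low cut (default 4): `AGREE_LOW` — the panel
#'   rejects the proposed classification;
#' * median in the uncertain band (default 4..<7): `NO_AGREEMENT`;
#' * median at or above the high cut: `AGREE_HIGH` when `IQR <= IPRAS`,
#'   `NO_AGREEMENT` when the spread exceeds IPRAS.
#'
#' An IQR exactly equal to IPRAS counts as agreement (disagreement
#' requires spread strictly greater than the threshold).
#'
#' @param scores Integer vector of Likert scores in 1..9, optionally
#'   named by panelist.
#' @param config An [agreement_config()].
#' @return An object of class `agreement_result`: list with `n`,
#'   `median`, `q1`, `q3`, `iqr`, `iprcp` (inter-percentile midpoint),
#'   `asymmetry`, `ipras`, `status` (one of `"AGREE_HIGH"`,
#'   `"AGREE_LOW"`, `"NO_AGREEMENT"`), and `agreed` (logical).
#' @examples
#' classify_round(rep(9, 18))               # unanimous endorsement
#' classify_round(c(rep(1, 6), rep(9, 12))) # polarized: no agreement
#' @export
classify_round <- function(scores, config = agreement_config()) {
  scores <- .check_scores(scores)
  q <- score_quartiles(scores, config)
  iqr <- unname(q["q3"] - q["q1"])
  iprcp <- unname((q["q1"] + q["q3"]) / 2)
  ipras_val <- ipras(unname(q["q1"]), unname(q["q3"]), config)
  med <- unname(q["median"])
  status <- if (med < config$median_low_cut) {
    if (config$symmetric_low_rule && iqr > ipras_val) "NO_AGREEMENT" else "AGREE_LOW"
  } else if (med < config$median_high_cut) {
    "NO_AGREEMENT"
  } else if (iqr > ipras_val) {
    "NO_AGREEMENT"
  } else {
    "AGREE_HIGH"
  }
  structure(
    list(n = length(scores), median = med,
         q1 = unname(q["q1"]), q3 = unname(q["q3"]), iqr = iqr,
         iprcp = iprcp, asymmetry = abs(config$ipras_center - iprcp),
         ipras = ipras_val, status = status,
         agreed = status != "NO_AGREEMENT"),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Panel agreement (n = %d votes)\n  median %.2f  q1 %.2f  q3 %.2f  IQR %.2f  IPRAS %.2f\n  status: %s\n",
    x$n, x$median, x$q1, x$q3, x$iqr, x$ipras, x$status))
  invisible(x)
}

# Vectorized classification over many codes at once: `scores` is an
# integer vector, `code` a parallel grouping vector. Returns one row per
# code. This is the path the round engine uses at 16k-code scale.
.classify_many <- function(code, scores, config = agreement_config()) {
  scores <- .check_scores(scores)
  counts <- table(factor(code, levels = unique(code)),
                  factor(scores, levels = 1:9))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), NULL))
  n <- rowSums(counts)
  cum <- t(apply(counts, 1L, cumsum))
  ostat <- function(k) {
    # per-row order statistic at per-row rank k (vector)
    1L + rowSums(cum < k)
  }
  qn <- function(p) {
    h <- 1 + (n - 1) * p
    if (config$quantile_method == "nearest") {
      return(ostat(pmin(n, pmax(1, floor(h + 0.5)))))
    }
    lo <- floor(h)
    g <- h - lo
    x_lo <- ostat(lo)
    x_hi <- ostat(pmin(n, lo + 1))
    (1 - g) * x_lo + g * x_hi
  }
  q1 <- qn(config$quantile_lo)
  med <- qn(0.5)
  q3 <- qn(config$quantile_hi)
  iqr <- q3 - q1
  ipras_val <- config$ipras_base +
    config$ipras_slope * abs(config$ipras_center - (q1 + q3) / 2)
  status <- ifelse(
    med < config$median_low_cut,
    ifelse(config$symmetric_low_rule & iqr > ipras_val, "NO_AGREEMENT", "AGREE_LOW"),
    ifelse(med < config$median_high_cut, "NO_AGREEMENT",
           ifelse(iqr > ipras_val, "NO_AGREEMENT", "AGREE_HIGH")))
  data.frame(code = rownames(counts), n = n, median = med, q1 = q1, q3 = q3,
             iqr = iqr, ipras = ipras_val, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}
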