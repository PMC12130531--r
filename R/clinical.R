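#' Immunohistochemistry H-score
#'
#' `H = 0*P0 + 1*P1 + 2*P2 + 3*P3`, where `P0..P3` are the percentages of
#' cells staining at intensity 0 (none), 1 (weak), 2 (moderate) and 3
#' (strong). Range 0--300. Vectorized over cases.
#'
#' @param p0,p1,p2,p3 Percentages in `[0, 100]`; each case must sum to 100
#'   (tolerance 1e-9).
#' @return Numeric vector of H-scores.
#' @examples
#' h_score(10, 20, 30, 40) # 200
#' @export
h_score <- function(p0, p1, p2, p3) {
  prof <- cbind(p0, p1, p2, p3)
  if (any(!is.finite(prof)) || any(prof < 0 | prof > 100)) {
    abort_validation("intensity percentages must lie in [0, 100]")
  }
  tot <- rowSums(prof)
  bad <- abs(tot - 100) > 1e-9
  if (any(bad)) {
    abort_validation(sprintf(
      "intensity percentages must sum to 100 (case(s) %s sum to %s)",
      paste(head(which(bad), 5), collapse = ", "),
      paste(head(format(tot[bad]), 5), collapse = ", ")
    ))
  }
  as.numeric(prof %*% c(0, 1, 2, 3))
}

#' Score a table of IHC cases
#'
#' Adds an `h_score` column computed from columns `P0`, `P1`, `P2`, `P3`.
#'
#' @param cases Data frame with columns `P0..P3` (and any id/covariate
#'   columns, which pass through untouched).
#' @return The input as a tibble with an `h_score` column appended.
#' @export
score_cases <- function(cases) {
  cases <- as_tibble(cases)
  need <- c("P0", "P1", "P2", "P3")
  miss <- setdiff(need, names(cases))
  if (length(miss) > 0) {
    abort_format(sprintf("cases table lacks column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  cases$h_score <- h_score(cases$P0, cases$P1, cases$P2, cases$P3)
  cases
}

#' 2x2 association test for marker-by-group tables
#'
#' Tests independence of a dichotomized marker (rows: high/low) against a
#' two-level grouping (columns), the arithmetic behind marker-vs-subtype
#' contingency comparisons. `method = "auto"` applies the usual rule:
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' the (uncorrected) Pearson chi-square; `chi2_yates` applies the
#' continuity correction; Fisher's two-sided p is the hypergeometric sum
#' of tables no more probable than the observed one (via
#' [stats::fisher.test()]). The odds ratio is the sample cross-product
#' `ad/bc`.
#'
#' @param counts Either a 2x2 matrix (rows high/low, columns the groups)
#'   or a length-4 vector `c(high1, low1, high2, low2)` (column-major).
#' @param method One of `"auto"`, `"chi2"`, `"chi2_yates"`, `"fisher"`.
#' @return One-row tibble: `method` (test actually used), `statistic`
#'   (chi-square statistic; `NA` for Fisher), `p`, `odds_ratio`,
#'   `prop_high_1`, `prop_high_2` (column percentages of the high row,
#'   full precision) and `display` (the proportions rounded to one
#'   decimal for reporting).
#' @examples
#' association_test(c(24, 98, 42, 89)) # 19.7% vs 32.1%
#' @export
association_test <- function(counts,
                             method = c("auto", "chi2", "chi2_yates", "fisher")) {
  method <- match.arg(method)
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 2)
  if (!all(dim(m) == c(2, 2))) abort_validation("counts must form a 2x2 table")
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    abort_validation("counts must be non-negative integers")
  }
  if (sum(m) == 0) abort_validation("all-zero table")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  used <- if (method == "auto") {
    if (any(expected < 5)) "fisher" else "chi2"
  } else {
    method
  }
  if (used == "fisher") {
    ft <- fisher.test(m)
    statistic <- NA_real_
    p <- ft$p.value
  } else {
    ct <- suppressWarnings(chisq.test(m, correct = used == "chi2_yates"))
    statistic <- unname(ct$statistic)
    p <- ct$p.value
  }
  prop <- 100 * m[1, ] / colSums(m)
  tibble(
    method = used,
    statistic = statistic,
    p = p,
    odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
    prop_high_1 = prop[1],
    prop_high_2 = prop[2],
    display = sprintf("%.1f%% vs %.1f%%", round(prop[1], 1), round(prop[2], 1))
  )
}

#' Extreme-decile (or any extreme-fraction) dichotomization
#'
#' Splits samples into low and high groups of size
#' `k = round-half-up(fraction * n)` each, taken from the bottom and top
#' of the value ordering (e.g. top and bottom 10% of 415 samples gives
#' 42 per group). Ties at a boundary are broken by stable input order.
#'
#' @param values Numeric vector, no missing values.
#' @param ids Sample identifiers (default `names(values)` or indices).
#' @param fraction Fraction per tail, `0 < fraction < 0.5`.
#' @return Tibble with columns `sample`, `value`, `group`
#'   (`"low"`/`"high"`), `2k` rows; attribute `k` records the group size.
#' @examples
#' dichotomize_extremes(rnorm(415), fraction = 0.10) # 42 per group
#' @export
dichotomize_extremes <- function(values, ids = NULL, fraction = 0.10) {
  check_number(fraction, "fraction", 0, 0.5, open_lower = TRUE,
               open_upper = TRUE)
  if (any(is.na(values))) abort_validation("values must have no missing entries")
  n <- length(values)
  if (is.null(ids)) ids <- names(values) %||% as.character(seq_len(n))
  if (length(ids) != n) abort_validation("ids must match values in length")
  if (fraction * n < 1) {
    abort_validation("fraction * n is below 1; no group can be formed")
  }
  k <- floor(fraction * n + 0.5)  # round half up
  if (2 * k > n) abort_validation("extreme groups would overlap")
  o <- order(values)  # stable: ties keep input order
  sel <- c(o[seq_len(k)], o[seq.int(n - k + 1L, n)])
  out <- tibble(
    sample = ids[sel],
    value = values[sel],
    group = rep(c("low", "high"), each = k)
  )
  attr(out, "k") <- k
  out
}

#' Export scored cases for external survival analysis
#'
#' Survival fitting itself (Kaplan--Meier, Cox) is deliberately out of
#' scope; this returns a tidy frame (case id, H-score, high/low group,
#' remaining covariates) ready for the survival tools of your choice.
#'
#' @param cases Output of [score_cases()].
#' @param cutoff H-score cutoff; cases strictly above it are `"high"`.
#' @return Tibble with `h_group` prepended after the H-score.
#' @export
export_survival_frame <- function(cases, cutoff) {
  if (!"h_score" %in% names(cases)) cases <- score_cases(cases)
  check_number(cutoff, "cutoff", 0, 300)
  cases$h_group <- ifelse(cases$h_score > cutoff, "high", "low")
  as_tibble(cases)
}
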