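#' Chi-square test of Mendelian segregation ratios
#'
#' Tests observed genotype counts from a heterozygote intercross against
#' an expected segregation ratio (1:2:1 by default) with expected counts
#' derived from the observed total.
#'
#' @param counts Integer vector of genotype counts (e.g. `+/+`, `mut/+`,
#'   `mut/mut`), total > 0.
#' @param ratio Expected ratio, same length as `counts`, all components
#'   > 0 (a zero expected class is degenerate and rejected).
#'
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
mendelian_test <- function(counts, ratio = c(1, 2, 1)) {
  if (length(counts) != length(ratio))
    stop("`counts` and `ratio` must have the same length")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) <= 0) stop("total count must be > 0")
  if (any(ratio <= 0))
    stop("all ratio components must be > 0 (zero expected cell)")
  ht <- stats::chisq.test(counts, p = ratio / sum(ratio))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = unname(ht$expected))
}

#' Observed genotype counts as percent of Mendelian expectation
#'
#' Two conventions for the expected counts are provided: `"total"`
#' (default) distributes the observed total according to the ratio, the
#' standard chi-square convention; `"wildtype"` anchors the expectation on
#' the observed wild-type (first) class, scaling the ratio so the
#' wild-type class is at 100 percent.
#'
#' @param counts Integer vector of genotype counts.
#' @param ratio Expected segregation ratio (> 0).
#' @param anchor `"total"` or `"wildtype"`.
#'
#' @return Numeric vector: each genotype's observed count as percent of
#'   its expected count.
#' @export
observed_over_expected <- function(counts, ratio = c(1, 2, 1),
                                   anchor = c("total", "wildtype")) {
  anchor <- match.arg(anchor)
  if (length(counts) != length(ratio))
    stop("`counts` and `ratio` must have the same length")
  if (any(ratio <= 0)) stop("all ratio components must be > 0")
  expected <- if (anchor == "total") {
    if (sum(counts) <= 0) stop("total count must be > 0")
    sum(counts) * ratio / sum(ratio)
  } else {
    if (counts[1] <= 0) stop("wild-type anchor requires counts[1] > 0")
    counts[1] * ratio / ratio[1]
  }
  100 * counts / expected
}

#' Filter differentially expressed proteins by effect size and p-value
#'
#' Partitions records into up- and downregulated sets using strict
#' inequalities: upregulated requires `log2fc > lfc_threshold` and
#' `p < p_threshold`; downregulated requires `log2fc < -lfc_threshold`
#' and `p < p_threshold`. A record at the boundary is excluded. No
#' multiple-testing correction is applied.
#'
#' @param records Data frame with columns `log2fc` and `p` (and any id
#'   columns, carried through).
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @param p_threshold Raw p-value threshold.
#'
#' @return List with data frames `up` and `down` (disjoint subsets of
#'   `records`).
#' @export
dep_filter <- function(records, lfc_threshold = 0.5, p_threshold = 0.05) {
  if (!all(c("log2fc", "p") %in% names(records)))
    stop("`records` must have columns `log2fc` and `p`")
  if (any(!is.finite(records$log2fc)) ||
      any(!is.finite(records$p)))
    stop("`log2fc` and `p` must be finite")
  if (any(records$p <= 0 | records$p > 1))
    stop("p-values must lie in (0, 1]")
  sig <- records$p < p_threshold
  list(up = records[sig & records$log2fc > lfc_threshold, , drop = FALSE],
       down = records[sig & records$log2fc < -lfc_threshold, , drop = FALSE])
}
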