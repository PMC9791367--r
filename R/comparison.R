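# Per-focal-gene summaries and the cis-vs-trans statistical contrasts.

measure_columns <- function(measure) {
  switch(measure,
         count = list(pair = "trans_count", cis = "cis_count"),
         parallel_count = list(pair = "parallel_count", cis = "cis_count"),
         euclidean = list(pair = "trans_euclidean", cis = "cis_euclidean"),
         stop("unknown measure: ", measure))
}

#' Per-focal-gene cis/trans pleiotropy summaries
#'
#' For each focal gene, the cis pleiotropy value, the median pleiotropy of
#' its trans-regulatory deletions (standard midpoint median for even
#' counts), and their difference (median trans minus cis).
#'
#' @param pairs A [cis_trans_pairs()] table (possibly filtered).
#' @param records A [pleiotropy_records()] table covering every focal gene
#'   appearing in `pairs`.
#' @param measure One of `"count"`, `"parallel_count"`, `"euclidean"`. For
#'   `"parallel_count"` the cis value is the cis DE-gene count (the cis
#'   deletion has no nested component to remove).
#' @return data.frame with columns `focal`, `cis_value`,
#'   `median_trans_value`, `difference`, `n_trans`, ordered by focal
#'   identifier (invariant to pair order).
#' @export
focal_summaries <- function(pairs, records,
                            measure = c("count", "parallel_count",
                                        "euclidean")) {
  measure <- match.arg(measure)
  cols <- measure_columns(measure)
  missing <- setdiff(unique(pairs$focal), records$gene)
  if (length(missing) > 0L)
    stop("no pleiotropy record for focal gene(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  val <- pairs[[cols$pair]]
  drop <- is.na(val)
  if (any(drop)) {
    lost <- setdiff(unique(pairs$focal[drop]), unique(pairs$focal[!drop]))
    if (length(lost) > 0L)
      warning(sprintf("%d focal gene(s) excluded: all pair values missing",
                      length(lost)))
    pairs <- pairs[!drop, , drop = FALSE]
    val <- val[!drop]
  }
  fg <- sort(unique(pairs$focal))
  med <- vapply(split(val, factor(pairs$focal, levels = fg)),
                stats::median, numeric(1))
  cis <- records[[cols$cis]][match(fg, records$gene)]
  data.frame(focal = fg, cis_value = cis, median_trans_value = as.numeric(med),
             difference = as.numeric(med) - cis,
             n_trans = as.integer(table(factor(pairs$focal, levels = fg))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sample, one-sided t test of differences against zero
#'
#' Tests whether the mean of the per-focal-gene differences (median trans
#' pleiotropy minus cis pleiotropy) exceeds zero; returns the upper-tail
#' p-value.
#'
#' @param differences Numeric vector, length >= 2, nonzero variance.
#' @return List with `t`, `df`, `p`.
#' @export
one_sided_difference_test <- function(differences) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 2L)
    stop("need at least 2 differences")
  if (stats::sd(differences) == 0)
    stop(paste("differences have zero variance; use a sign or permutation",
               "test instead"))
  ht <- stats::t.test(differences, mu = 0, alternative = "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sample t test with a two-sided p-value, used to
#' compare pleiotropy-difference distributions (e.g. cis values against
#' per-focal median trans values on a permuted network).
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_difference_test <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("both samples must have at least 2 values")
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b))))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    stop("both samples are constant; the Welch statistic is undefined")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Proportion of focal genes (or pairs) where cis pleiotropy is greater
#'
#' Strict inequality: ties count as "not greater".
#'
#' @param x For `mode = "per_focal"`, a [focal_summaries()] table; for
#'   `"per_pair"`, a [cis_trans_pairs()] table.
#' @param mode Comparison granularity.
#' @param measure Measure used (needed in `per_pair` mode to pick columns).
#' @param records [pleiotropy_records()] table (required in `per_pair`
#'   mode, supplying the cis values).
#' @return List with `numerator`, `denominator`, `proportion`.
#' @export
proportion_cis_greater <- function(x, mode = c("per_focal", "per_pair"),
                                   measure = c("count", "parallel_count",
                                               "euclidean"),
                                   records = NULL) {
  mode <- match.arg(mode)
  measure <- match.arg(measure)
  if (mode == "per_focal") {
    if (nrow(x) == 0L) stop("empty summary table")
    num <- sum(x$cis_value > x$median_trans_value)
    den <- nrow(x)
  } else {
    if (is.null(records))
      stop("per_pair mode requires the per-gene records table")
    cols <- measure_columns(measure)
    cis <- records[[cols$cis]][match(x$focal, records$gene)]
    val <- x[[cols$pair]]
    keep <- !is.na(val) & !is.na(cis)
    if (!any(keep)) stop("no comparable pairs")
    num <- sum(cis[keep] > val[keep])
    den <- sum(keep)
  }
  list(numerator = as.integer(num), denominator = as.integer(den),
       proportion = num / den)
}
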