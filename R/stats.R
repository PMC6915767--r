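#' Aggregate per-object measurements to one value per animal
#'
#' Statistics are always computed over animals (or human cases), never
#' over individual synapses: the experimental unit is the subject.
#' Downstream tests consume these per-animal summaries only.
#'
#' @param df data frame with an `animal_id` column and the metric.
#' @param metric name of the metric column.
#' @param statistic `"mean"` or `"median"`.
#' @param group_cols optional character vector of grouping label
#'   columns (genotype, treatment, near/far stratum, ...) carried
#'   through; must be constant within animal x stratum.
#' @return data frame: `animal_id`, group columns, `value`
#'   (one row per animal per group combination).
#' @export
aggregate_per_animal <- function(df, metric, statistic = c("mean", "median"),
                                 group_cols = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(df), "animal_id" %in% names(df),
            metric %in% names(df))
  if (nrow(df) == 0L) stop("empty table: no animals to aggregate")
  fun <- if (statistic == "mean") mean else median
  by <- df[, c("animal_id", group_cols), drop = FALSE]
  agg <- aggregate(df[[metric]], by = by, FUN = fun)
  names(agg)[ncol(agg)] <- "value"
  agg <- agg[do.call(order, agg[, c("animal_id", group_cols), drop = FALSE]), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The p-value is
#' exact (distribution of U under the permutation null) when the
#' combined sample size is at most `exact_max` and there are no ties;
#' otherwise the normal approximation with tie correction and
#' continuity correction is used. If every value in both groups is
#' identical the test is degenerate and p = 1.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @param exact_max largest combined n for which the exact branch is
#'   used (default 12).
#' @return list: `U` (statistic for `group_a`), `p`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b, alternative = "two.sided",
                           exact_max = 12L) {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L,
            is.numeric(group_a), is.numeric(group_b))
  n_a <- length(group_a); n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)                           # midranks
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L) {
    return(list(U = U, p = 1, method = "degenerate", n_a = n_a, n_b = n_b))
  }
  use_exact <- !ties && (n_a + n_b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  stopifnot(abs(unname(wt$statistic) - U) < 1e-8)
  at_log("mann_whitney_u: n=(%d,%d) branch=%s", n_a, n_b,
         if (use_exact) "exact" else "normal_approx", level = "debug")
  list(U = U, p = unname(wt$p.value),
       method = if (use_exact) "exact" else "normal_approx",
       n_a = n_a, n_b = n_b)
}

#' Chi-square goodness-of-fit test against expected proportions
#'
#' `chi2 = sum((O - E)^2 / E)` with `E = n * p`; the p-value is the
#' upper-tail chi-square probability at `k - 1` degrees of freedom.
#' Used e.g. to confirm Mendelian inheritance ratios of transgene
#' combinations.
#'
#' @param observed_counts non-negative integer counts per class.
#' @param expected_proportions probabilities summing to 1, all > 0.
#' @return list: `chi2`, `df`, `p`.
#' @export
chi_square_gof <- function(observed_counts,
                           expected_proportions = rep(1 / length(observed_counts),
                                                      length(observed_counts))) {
  stopifnot(length(observed_counts) == length(expected_proportions),
            all(observed_counts >= 0))
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop("expected proportions must sum to 1")
  }
  if (any(expected_proportions <= 0)) {
    stop("expected proportions must all be positive (no zero expected counts)")
  }
  k <- length(observed_counts)
  n <- sum(observed_counts)
  E <- n * expected_proportions
  chi2 <- sum((observed_counts - E)^2 / E)
  df <- k - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Upper-tail chi-square probability
#'
#' Convenience wrapper reporting P(X >= x) for X ~ chi-square(df), the
#' quantity printed alongside a chi-square statistic.
#'
#' @param x statistic value.
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
chi_square_upper_tail <- function(x, df) {
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment (off by default in the pipeline)
#'
#' @param p vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
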