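#' Kruskal-Wallis one-way analysis of variance on ranks
#'
#' Rank-based H statistic with tie correction and a chi-squared p-value on
#' k - 1 degrees of freedom; the workhorse significance test for PLM
#' distributions, which are far from normal (many axons at 0, a mode near
#' full coverage).
#'
#' @param groups List of at least 2 non-empty numeric vectors, or a single
#'   numeric vector with `g` giving group labels.
#' @param g Optional grouping vector when `groups` is a numeric vector.
#' @return List with `H`, `p`, and `df`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  if (!is.list(groups) || length(groups) < 2L ||
      any(vapply(groups, length, integer(1)) < 1L)) {
    stop_myelo("need at least 2 non-empty groups", "myelo_argument_error")
  }
  x <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1L) {
    # all observations tied: no rank variation, H = 0 by convention
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(x, lab)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn-Sidak multiple-comparison correction
#'
#' Corrects a raw p-value for a family of `m` comparisons:
#' `1 - (1 - p)^m`, clipped to \[0, 1\]. `m` should be the number of
#' pairwise comparisons actually performed in the family (15 for six
#' groups), not a global constant.
#'
#' @param p_raw Raw p-value(s) in \[0, 1\] (vectorized).
#' @param m Number of comparisons in the family, >= 1.
#' @return Corrected p-value(s).
#' @examples
#' dunn_sidak(0.01, 15)  # 0.1399
#' @export
dunn_sidak <- function(p_raw, m) {
  if (any(p_raw < 0 | p_raw > 1)) {
    stop_myelo("p values must lie in [0, 1]", "myelo_argument_error")
  }
  if (any(m < 1)) stop_myelo("m must be >= 1", "myelo_argument_error")
  pmin(1, pmax(0, 1 - (1 - p_raw)^m))
}

#' Dunn's post-hoc pairwise comparisons with Sidak correction
#'
#' After a Kruskal-Wallis test, compares every pair of groups by the
#' difference in mean pooled rank. The standard error of a rank-mean
#' difference under the null is
#' `sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))` with tie term
#' `T = sum(t^3 - t) / (12 (N - 1))`; z-based two-sided p-values are
#' Sidak-corrected for the `choose(k, 2)` comparisons, and confidence
#' intervals on the rank-mean difference use the Sidak-adjusted critical
#' value so interval and corrected p agree.
#'
#' @param groups Named list of numeric vectors (names label the samples).
#' @param conf Familywise interval coverage; default 0.95.
#' @return Data frame with columns `sample_1`, `sample_2`, `ci_lower`,
#'   `estimate` (rank-mean difference), `ci_upper`, `corrected_p`.
#' @export
dunn_posthoc <- function(groups, conf = 0.95) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_myelo("need at least 2 groups", "myelo_argument_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  n_i <- vapply(groups, length, integer(1))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, rep(names(groups), n_i), mean)[names(groups)]
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  k <- length(groups)
  m <- k * (k - 1) / 2
  alpha_sidak <- 1 - conf^(1 / m)  # per-comparison level with Sidak control
  zcrit <- stats::qnorm(1 - alpha_sidak / 2)
  pairs <- utils::combn(names(groups), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- rbar[[a]] - rbar[[b]]
    se <- sqrt(s2 * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z <- est / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    data.frame(sample_1 = a, sample_2 = b,
               ci_lower = est - zcrit * se, estimate = est,
               ci_upper = est + zcrit * se,
               corrected_p = dunn_sidak(p_raw, m))
  })
  do.call(rbind, out)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum distance between the two empirical CDFs with the asymptotic
#' p-value; used to compare e.g. diameter distributions of myelinated
#' versus unmyelinated axons.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop_myelo("both samples must be non-empty", "myelo_argument_error")
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Paired t-test
#'
#' Standard paired t on the within-pair differences. All-zero differences
#' return `t = 0, p = 1` (no change whatsoever); non-zero constant
#' differences have zero variance and raise, since the statistic is
#' undefined there.
#'
#' @param a,b Equal-length numeric vectors with at least 2 pairs.
#' @param two_tailed Logical; default `TRUE`.
#' @return List with `t`, `p`, and `df`.
#' @export
paired_t <- function(a, b, two_tailed = TRUE) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop_myelo("paired t needs equal-length samples with >= 2 pairs",
               "myelo_argument_error")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1L))
    stop_myelo("differences have zero variance: t statistic undefined",
               "myelo_degenerate_error")
  }
  tt <- stats::t.test(a, b, paired = TRUE,
                      alternative = if (two_tailed) "two.sided" else "greater")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Kruskal-Wallis with Dunn-Sidak post hoc on a long-format table
#'
#' Convenience wrapper producing the omnibus test plus the pairwise
#' comparison table (`sample_1 sample_2 ci_lower estimate ci_upper
#' corrected_p`) in one call.
#'
#' @param data Data frame with columns `group` and `value`.
#' @return List with `kruskal` (see [kruskal_wallis()]) and `pairwise`
#'   (see [dunn_posthoc()]).
#' @export
compare_groups <- function(data) {
  if (!all(c("group", "value") %in% names(data))) {
    stop_myelo("data needs columns 'group' and 'value'", "myelo_argument_error")
  }
  groups <- split(as.numeric(data$value), as.character(data$group))
  list(kruskal = kruskal_wallis(groups), pairwise = dunn_posthoc(groups))
}
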