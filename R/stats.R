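# Statistical layer: pooled-SD standardized mean differences, large-sample
# confidence intervals, exact Wilcoxon tests with mid-ranks, and the Holm
# step-down multiple-comparison adjustment.

#' Group summary (n, mean, SD)
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (>= 0).
#' @param n number of observations (>= 2).
#' @return list of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  assert_scalar_number(sd, "sd", 0)
  assert_scalar_number(n, "n", 2)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Summarize a numeric sample
#'
#' @param x numeric vector with at least two values.
#' @return a [group_summary()].
#' @export
summarize_group <- function(x) {
  if (length(x) < 2L) stop("need at least two observations", call. = FALSE)
  group_summary(mean(x), stats::sd(x), length(x))
}

#' Pooled standard deviation of two groups
#'
#' `Sw = sqrt(((n1-1) S1^2 + (n2-1) S2^2) / (n1 + n2 - 2))`.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return the pooled SD.
#' @export
#' @examples
#' pooled_sd(group_summary(16.57, 6.76, 30), group_summary(5.03, 3.56, 30))
pooled_sd <- function(g1, g2) {
  if (g1$n + g2$n <= 2L) stop("degenerate group sizes", call. = FALSE)
  sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2))
}

#' Standardized mean difference (pooled-SD Cohen d)
#'
#' `d = (mean1 - mean2) / Sw` with the pooled SD of [pooled_sd()], plus a
#' large-sample confidence interval (see [cohens_d_ci()]).
#'
#' @param g1,g2 [group_summary()] objects.
#' @param level confidence level for the interval (default 0.95).
#' @return object of class `effect_size`: list with `d`, `sw`, `ci_low`,
#'   `ci_high`, `level`, `n1`, `n2`.
#' @export
#' @examples
#' cohens_d(group_summary(16.57, 6.76, 30), group_summary(5.03, 3.56, 30))$d
cohens_d <- function(g1, g2, level = 0.95) {
  sw <- pooled_sd(g1, g2)
  if (sw == 0) stop("pooled SD is zero; effect size undefined", call. = FALSE)
  d <- (g1$mean - g2$mean) / sw
  ci <- cohens_d_ci(d, g1$n, g2$n, level)
  structure(list(d = d, sw = sw, ci_low = ci[1], ci_high = ci[2],
                 level = level, n1 = g1$n, n2 = g2$n),
            class = "effect_size")
}

#' Large-sample confidence interval for a standardized mean difference
#'
#' `d +/- z * sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))` with
#' `z` the standard-normal quantile at `(1 + level)/2`.
#'
#' @param d the standardized mean difference.
#' @param n1,n2 group sizes.
#' @param level confidence level in (0, 1).
#' @return numeric vector `c(low, high)`.
#' @export
cohens_d_ci <- function(d, n1, n2, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0,1)", call. = FALSE)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm((1 + level) / 2)
  c(d - z * se, d + z * se)
}

#' Contrast between two effect sizes
#'
#' The difference `d_a - d_b`, with each input signed so that an error
#' decrease is positive and an error increase negative.
#'
#' @param d_a,d_b standardized mean differences (numbers or
#'   `effect_size` objects).
#' @return `d_a - d_b`.
#' @export
#' @examples
#' d_contrast(2.137, -0.512) # 2.649
d_contrast <- function(d_a, d_b) {
  num <- function(x) if (inherits(x, "effect_size")) x$d else x
  num(d_a) - num(d_b)
}

# Exact tail probabilities of a sum over subsets.  `weights` are doubled
# mid-ranks (integers).  Returns the counts of achievable sums when each
# weight is independently included/excluded (signed-rank null).
signed_rank_counts <- function(weights) {
  total <- sum(weights)
  counts <- c(1, rep(0, total))     # counts[s + 1] = #assignments with sum s
  for (w in weights) {
    shifted <- c(rep(0, w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test (exact for small samples, mid-ranks for ties)
#'
#' Zero differences are dropped; absolute differences receive mid-ranks.
#' With at most `exact_limit` informative pairs the two-sided p-value is
#' computed from the exact null distribution over all sign assignments;
#' beyond that a normal approximation with tie correction and continuity
#' correction is used.  Two-sided p is `min(1, 2 min(lower, upper))`.
#'
#' @param x numeric vector (differences, or first paired sample).
#' @param y optional second paired sample; the test is on `x - y`.
#' @param exact_limit maximum informative pairs for exact enumeration
#'   (default 25).
#' @return object of class `rank_test`: list with `statistic` (V, the sum
#'   of positive-difference ranks), `p_value`, `method`, `exact`, `n`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(structure(list(statistic = 0, p_value = 1,
                          method = "signed-rank", exact = TRUE, n = 0L),
                     class = "rank_test"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    w2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(w2)
    totals <- sum(counts)
    s <- as.integer(round(2 * v))
    lower <- sum(counts[seq_len(s + 1L)]) / totals
    upper <- sum(counts[(s + 1L):length(counts)]) / totals
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = v, p_value = p, method = "signed-rank",
                 exact = exact, n = n),
            class = "rank_test")
}

# Distribution of the rank-sum of group A over all C(n, n1) labelings.
# `weights` are doubled mid-ranks; returns matrix counts[k + 1, s + 1].
rank_sum_counts <- function(weights, n1) {
  total <- sum(weights)
  counts <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  counts[1, 1] <- 1
  for (w in weights) {
    for (k in n1:1) {
      nonzero <- which(counts[k, ] > 0)
      if (length(nonzero)) {
        counts[k + 1L, nonzero + w] <- counts[k + 1L, nonzero + w] +
          counts[k, nonzero]
      }
    }
  }
  counts
}

#' Wilcoxon rank-sum test (exact for small groups, mid-ranks for ties)
#'
#' The statistic is the rank sum of the first sample in the pooled
#' mid-ranking.  For groups of at most `exact_limit` each, the two-sided
#' p-value is computed from the exact permutation distribution over all
#' group labelings; otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_limit maximum per-group size for exact enumeration
#'   (default 10).
#' @return a `rank_test` (see [wilcoxon_signed_rank()]) with
#'   `method = "rank-sum"`.
#' @export
rank_sum <- function(x, y, exact_limit = 10L) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_limit && n2 <= exact_limit) {
    w2 <- as.integer(round(2 * r))
    counts <- rank_sum_counts(w2, n1)[n1 + 1L, ]
    totals <- sum(counts)
    s <- as.integer(round(2 * w))
    lower <- sum(counts[seq_len(s + 1L)]) / totals
    upper <- sum(counts[(s + 1L):length(counts)]) / totals
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = w, p_value = p, method = "rank-sum",
                 exact = exact, n = c(n1, n2)),
            class = "rank_test")
}

#' Holm step-down adjustment of p-values
#'
#' Step-down Bonferroni adjustment with monotonicity enforcement; adjusted
#' values are at least the raw ones and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03)) # 0.03 0.04 0.04
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Express a mean error count as a percentage of the material's word total
#'
#' `100 * mean_count / sum(word counts)`, where the word counts are those
#' of every text part the readers were exposed to.
#'
#' @param mean_count mean number of misread words.
#' @param text_counts numeric vector (or list) of per-part word counts.
#' @return percentage.
#' @export
#' @examples
#' percent_of_total(16.57, c(29, 30, 33, 34, 26, 25, 20, 19)) # 7.67
percent_of_total <- function(mean_count, text_counts) {
  total <- sum(unlist(text_counts))
  if (total <= 0) stop("total word count must be positive", call. = FALSE)
  100 * mean_count / total
}
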