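test_that("pooled SD follows the square-root pooled formula", {
  # equal SDs pool to themselves regardless of n
  expect_equal(pooled_sd(group_summary(1, 4, 12), group_summary(9, 4, 7)), 4)
  expect_equal(pooled_sd(group_summary(16.57, 6.76, 30),
                         group_summary(5.03, 3.56, 30)),
               5.402, tolerance = 0.001 / 5.402)
  expect_equal(pooled_sd(group_summary(0, 473.08, 19),
                         group_summary(0, 705.60, 18)),
               597.4, tolerance = 0.1 / 597.4)
  expect_error(pooled_sd(group_summary(0, 1, 2), group_summary(0, 1, 2)),
               NA)
})

test_that("standardized mean differences match direct evaluation", {
  d <- cohens_d(group_summary(16.57, 6.76, 30), group_summary(5.03, 3.56, 30))
  expect_equal(d$d, 2.137, tolerance = 0.01 / 2.137)
  # antisymmetry and zero for identical groups
  d_rev <- cohens_d(group_summary(5.03, 3.56, 30), group_summary(16.57, 6.76, 30))
  expect_equal(d_rev$d, -d$d)
  same <- cohens_d(group_summary(3, 1, 10), group_summary(3, 2, 10))
  expect_equal(same$d, 0)
  expect_error(cohens_d(group_summary(1, 0, 5), group_summary(2, 0, 5)))
})

test_that("effect sizes are invariant under common affine rescaling", {
  g1 <- group_summary(12.3, 4.1, 14)
  g2 <- group_summary(9.8, 3.3, 17)
  a <- 2.5; b <- -7
  g1s <- group_summary(a * g1$mean + b, a * g1$sd, g1$n)
  g2s <- group_summary(a * g2$mean + b, a * g2$sd, g2$n)
  expect_equal(cohens_d(g1s, g2s)$d, cohens_d(g1, g2)$d)
})

test_that("the large-sample interval behaves as stated", {
  ci <- cohens_d_ci(0, 100, 100, 0.95)
  expect_equal(ci[1], -ci[2])
  narrow <- cohens_d_ci(0.4, 1000, 1000)
  wide <- cohens_d_ci(0.4, 10, 10)
  expect_lt(diff(narrow), diff(wide))
  # direct evaluation of the formula
  d <- 0.5; n1 <- n2 <- 30
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  expect_equal(cohens_d_ci(d, n1, n2, 0.95),
               d + c(-1, 1) * qnorm(0.975) * se)
  expect_error(cohens_d_ci(0.5, 10, 10, 1.2))
})

test_that("effect-size contrasts subtract signed effects", {
  expect_equal(d_contrast(2.137, -0.512), 2.649)
  expect_equal(d_contrast(1.3, 1.3), 0)
  expect_equal(d_contrast(0.7, 0.2), -d_contrast(0.2, 0.7))
})

test_that("exact signed-rank p-values equal full enumeration", {
  set.seed(61)
  for (i in seq_len(40)) {
    n <- sample(3:8, 1)
    d <- round(rnorm(n, sd = 3), 1)
    d <- d[d != 0]
    if (length(d) < 2) next
    res <- wilcoxon_signed_rank(d)
    expect_true(res$exact)
    expect_equal(res$p_value, enum_signed_rank_p(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
  # ties handled through mid-ranks in both routes
  tied <- c(2, 2, -2, 3, 3, -1)
  expect_equal(wilcoxon_signed_rank(tied)$p_value, enum_signed_rank_p(tied))
})

test_that("signed-rank edge cases follow the contract", {
  expect_warning(res <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(res$p_value, 1)
  # strong one-sided shift attains the minimal two-sided p: 2 / 2^n
  strong <- wilcoxon_signed_rank(rep(5, 10) + (1:10) / 100)
  expect_equal(strong$p_value, 2 / 2^10)
  # identical pairs drop out entirely
  expect_warning(p_id <- wilcoxon_signed_rank(c(4, 7), c(4, 7))$p_value)
  expect_equal(p_id, 1)
  # large-sample route stays a valid probability
  set.seed(3)
  big <- wilcoxon_signed_rank(rnorm(60) + 0.2)
  expect_false(big$exact)
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("exact rank-sum p-values equal labeling enumeration", {
  set.seed(71)
  for (i in seq_len(30)) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1, sd = 2), 1)
    y <- round(rnorm(n2, 1, 2), 1)
    res <- rank_sum(x, y)
    expect_true(res$exact)
    expect_equal(res$p_value, enum_rank_sum_p(x, y), tolerance = 1e-12)
    # group swap leaves the two-sided p unchanged
    expect_equal(rank_sum(y, x)$p_value, res$p_value, tolerance = 1e-12)
  }
  expect_error(rank_sum(numeric(0), 1:3))
})

test_that("Holm adjustment matches its hand-stepped definition", {
  # hand-step: sorted (0.01, 0.03, 0.04) -> (3*0.01, max(.03, 2*0.03),
  # max(.06, 1*0.04)) = (0.03, 0.06, 0.06), mapped back to input order
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  set.seed(81)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, hand_holm(p), info = paste(round(p, 3), collapse = ","))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # permutation equivariance
    perm <- sample(seq_along(p))
    expect_equal(holm_bonferroni(p[perm]), adj[perm])
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)))
})

test_that("error percentages use the material's word total", {
  counts <- study_text_counts()$words
  expect_equal(percent_of_total(16.57, counts), 7.67, tolerance = 0.01 / 7.67)
  expect_equal(percent_of_total(14.4, counts), 6.67, tolerance = 0.01 / 6.67)
  expect_equal(percent_of_total(0, counts), 0)
  expect_error(percent_of_total(5, 0))
})
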