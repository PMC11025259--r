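# Enumeration oracles, independent of the implementations under test.
perm_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  combos <- utils::combn(n, nx)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Wilcoxon worked examples: separation, identity, rank invariance", {
  sep <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1)
  expect_true(sep$exact)
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)
  a <- c(0.3, 1.2, 2.5, 4.1); b <- c(0.9, 3.3, 5.2, 6.0)
  expect_equal(wilcoxon_rank_sum(exp(a), exp(b))$p_value,
               wilcoxon_rank_sum(a, b)$p_value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact Wilcoxon equals full permutation enumeration for n <= 12", {
  with_seed(7, {
    for (rep in 1:8) {
      nx <- sample(2:6, 1); ny <- sample(2:6, 1)
      x <- stats::rnorm(nx); y <- stats::rnorm(ny, mean = 0.5)
      expect_equal(wilcoxon_rank_sum(x, y)$p_value, perm_wilcoxon_p(x, y),
                   tolerance = 1e-10)
    }
  })
})

test_that("Fisher worked examples reproduce published contingency tables", {
  het <- fisher_exact(32, 63, 11, 41)
  expect_lt(abs(het$odds_ratio - 1.88), 0.01)  # 1.885 truncates to the printed 1.88
  expect_equal(round(het$p_value, 3), 0.131)
  expect_equal(round(fisher_exact(2, 52, 1, 101)$p_value, 3), 0.275)
  expect_equal(round(fisher_exact(39, 15, 69, 33)$p_value, 3), 0.589)
  bal <- fisher_exact(5, 5, 5, 5)
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(bal$p_value, 1)
  expect_error(fisher_exact(0, 0, 3, 4), "margin")
})

test_that("Fisher two-sided p equals hypergeometric enumeration (margins <= 30)", {
  with_seed(8, {
    for (rep in 1:12) {
      tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      got <- fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p_value
      expect_equal(got, enum_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1],
                                      tab[2, 2]), tolerance = 1e-9)
    }
  })
})

test_that("BH q-values match the step-up formula and preserve order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  with_seed(9, {
    for (rep in 1:20) {
      p <- stats::runif(50)
      q <- bh_fdr(p)
      # textbook step-up with monotonicity enforcement
      o <- order(p)
      manual <- p[o] * 50 / seq_len(50)
      manual <- rev(cummin(rev(manual)))
      expect_equal(q[o], pmin(manual, 1), tolerance = 1e-12)
      expect_true(all(diff(q[o]) >= -1e-12))
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("logit adjustment detects real effects and reacts to confounding", {
  with_seed(10, {
    n <- 400
    subtype <- sample(c("HRpos_HER2neg", "HER2pos", "TN"), n, replace = TRUE)
    group <- ifelse(stats::runif(n) < 0.5, "IBC", "nonIBC")
    feat <- as.numeric(group == "IBC") + stats::rnorm(n, sd = 0.5)
    res <- logit_adjusted(group, feat, subtype = subtype)
    expect_gt(res$odds_ratio, 1)
    expect_lt(res$p_value, 0.001)
    # confounded design: subtype drives both group and feature
    subtype2 <- sample(c("TN", "HRpos_HER2neg"), n, replace = TRUE)
    group2 <- ifelse(stats::runif(n) < ifelse(subtype2 == "TN", 0.8, 0.2),
                     "IBC", "nonIBC")
    feat2 <- as.numeric(subtype2 == "TN") * 2 + stats::rnorm(n)
    raw <- logit_adjusted(group2, feat2)
    adj <- logit_adjusted(group2, feat2, subtype = subtype2)
    expect_gt(abs(log(raw$odds_ratio)), abs(log(adj$odds_ratio)))
  })
})

test_that("complete separation is flagged as unreliable", {
  group <- rep(c("IBC", "nonIBC"), each = 20)
  feat <- as.numeric(group == "IBC")
  res <- logit_adjusted(group, feat)
  expect_false(res$reliable)
})

test_that("compare_feature dispatches by kind and assembles summaries", {
  group <- rep(c("IBC", "nonIBC"), c(52, 95))
  het <- c(rep(TRUE, 11), rep(FALSE, 41), rep(TRUE, 32), rep(FALSE, 63))
  res <- compare_feature(het, group, kind = "binary",
                         feature = "heterogeneous")
  expect_equal(res$test, "fisher")
  expect_equal(round(res$p_value, 3), 0.131)
  expect_match(res$summary_IBC, "11/52")
  x <- rep(c(1, 2, 3), 4)
  resc <- compare_feature(c(x, x), rep(c("IBC", "nonIBC"), each = 12),
                          kind = "continuous")
  expect_equal(resc$test, "wilcoxon")
  expect_equal(resc$p_value, 1, tolerance = 1e-9)
  expect_error(compare_feature(c(NA, NA, 1, 2),
                               c("IBC", "IBC", "nonIBC", "nonIBC"),
                               feature = "f"),
               "missing for an entire group")
})

test_that("feature families get a shared BH correction", {
  with_seed(12, {
    tab <- as.data.frame(matrix(stats::rnorm(40 * 5), 40))
    names(tab) <- paste0("f", 1:5)
    group <- rep(c("IBC", "nonIBC"), each = 20)
    res <- compare_features(tab, group, kind = "continuous")
    expect_equal(nrow(res), 5)
    expect_true(all(res$q_value >= res$p_value - 1e-12))
    expect_equal(res$q_value, bh_fdr(res$p_value))
  })
})
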