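# Monte-Carlo oracle for the Beta highest-density interval: narrowest
# window over sorted posterior draws.
mc_beta_hdi <- function(a, b, level = 0.95, n = 2e5) {
  x <- sort(stats::rbeta(n, a, b))
  k <- floor(level * n)
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

test_that("multiplicity rounds the corrected allele fraction with clamping", {
  expect_equal(estimate_multiplicity(0.5, 1, 4), 2L)
  expect_equal(estimate_multiplicity(0.25, 0.5, 2), 1L)
  expect_equal(estimate_multiplicity(0.01, 0.5, 2), 1L)   # clamped up to 1
  expect_equal(estimate_multiplicity(0.99, 1, 2), 2L)     # clamped to cn
  expect_error(estimate_multiplicity(0.5, 0.5, 0), "cn_total")
})

test_that("CCF algebra matches the purity/copy-number model", {
  expect_equal(compute_ccf(0.25, 0.5, 2, 1), 1.0)
  expect_equal(compute_ccf(0.125, 0.5, 2, 1), 0.5)
  expect_equal(compute_ccf(0.5, 1, 2, 1), 1.0)
  # the VAF that solves CCF = 1 maps back exactly
  purity <- 0.65; cn <- 3; m <- 2
  vaf1 <- purity * m / (purity * cn + 2 * (1 - purity))
  expect_equal(compute_ccf(vaf1, purity, cn, m), 1.0)
  # monotone in VAF; capped at 2 for reporting
  expect_lt(compute_ccf(0.1, 0.5, 2, 1), compute_ccf(0.2, 0.5, 2, 1))
  expect_equal(compute_ccf(0.9, 0.5, 2, 1), 2)
})

test_that("beta HDI agrees with the Monte-Carlo oracle", {
  with_seed(11, {
    for (ab in list(c(51, 51), c(6, 96), c(31, 71))) {
      hdi <- beta_hdi(ab[1], ab[2])
      mc <- mc_beta_hdi(ab[1], ab[2])
      expect_lt(abs(hdi[1] - mc[1]), 0.01)
      expect_lt(abs(hdi[2] - mc[2]), 0.01)
    }
  })
})

test_that("CCF credible intervals match known cases and shrink with depth", {
  # 50/50 reads, purity 1, diploid: HDI ~ [0.81, 1.19], contains 1
  hdi <- ccf_credible_interval(50, 50, 1, 2, 1)
  expect_lt(abs(hdi[1] - 0.81), 0.01)
  expect_lt(abs(hdi[2] - 1.19), 0.01)
  expect_true(hdi[1] <= 1 && 1 <= hdi[2])
  # 5/95: entirely below 1
  low <- ccf_credible_interval(5, 95, 1, 2, 1)
  expect_lt(low[2], 1)
  # width shrinks monotonically as depth grows at fixed VAF
  widths <- vapply(c(20, 80, 320, 1280), function(d) {
    h <- ccf_credible_interval(d / 2, d / 2, 1, 2, 1)
    h[2] - h[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(ccf_credible_interval(2, 3, 1, 2, 1),
               class = "wexscape_low_depth")
})

test_that("clonality labels follow the credible-interval rule", {
  expect_equal(classify_clonality(c(0.81, 1.19)), "Clonal")
  expect_equal(classify_clonality(c(0.10, 0.42)), "Subclonal")
  expect_equal(classify_clonality(c(1.05, 1.40)), "Clonal")
  expect_equal(classify_clonality(c(1.05, 1.40), strict = TRUE), "Subclonal")
})

test_that("CCF clustering finds the planted architecture", {
  calls1 <- with_seed(31, data.frame(
    sample_id = "S", cn_total = 2,
    ccf = stats::rnorm(60, 1, 0.03)))
  c1 <- cluster_ccfs(calls1, seed = 1)
  expect_equal(c1$k, 1)
  expect_false(c1$heterogeneous)
  calls2 <- with_seed(32, data.frame(
    sample_id = "S", cn_total = 2,
    ccf = c(stats::rnorm(50, 1, 0.05), stats::rnorm(50, 0.3, 0.05))))
  c2 <- cluster_ccfs(calls2, seed = 1)
  expect_equal(c2$k, 2)
  expect_equal(sort(c2$proportions), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sort(c2$means), c(0.3, 1.0), tolerance = 0.05)
})

test_that("clustering is invariant to input order and flags small samples", {
  calls <- with_seed(33, data.frame(
    sample_id = "S", cn_total = 2,
    ccf = c(stats::rnorm(40, 1, 0.05), stats::rnorm(40, 0.4, 0.05))))
  a <- cluster_ccfs(calls, seed = 2)
  b <- cluster_ccfs(calls[rev(seq_len(nrow(calls))), ], seed = 2)
  expect_equal(sort(a$means), sort(b$means))
  expect_equal(a$H, b$H)
  tiny <- cluster_ccfs(calls[1:5, ], seed = 2)
  expect_false(tiny$assessable)
  expect_true(is.na(tiny$H))
})

test_that("Shannon index closed forms and the H > 1 flag", {
  expect_equal(shannon_index(1)$H, 0)
  expect_false(shannon_index(1)$heterogeneous)
  h3 <- shannon_index(rep(1 / 3, 3))
  expect_equal(h3$H, log(3), tolerance = 1e-12)
  expect_true(h3$heterogeneous)
  h2 <- shannon_index(c(0.5, 0.5))
  expect_equal(h2$H, log(2), tolerance = 1e-12)
  expect_false(h2$heterogeneous)
  expect_error(shannon_index(c(0.5, 0.2)), "sum to 1")
})

test_that("clonal fractions summarize labels per sample", {
  calls <- data.frame(
    sample_id = rep(c("A", "B"), c(10, 4)),
    label = c(rep("Clonal", 8), rep("Subclonal", 2), rep("Clonal", 4)),
    stringsAsFactors = FALSE)
  samples <- as_samples(rbind(sample_row("A"),
                              sample_row("B", group = "nonIBC")))
  cf <- clonal_fraction_summary(calls, samples)
  expect_equal(cf$frac_clonal[cf$sample_id == "A"], 0.8)
  expect_equal(cf$frac_clonal[cf$sample_id == "B"], 1.0)
  expect_true(all(cf$frac_clonal + cf$frac_subclonal == 1))
})

test_that("cohort clonality calls exclude low-depth and homozygous-deletion sites", {
  muts <- as_mutations(rbind(
    mut_row("A", chrom = "chrT1", pos = 5e6, alt_count = 30, ref_count = 70),
    mut_row("A", chrom = "chrT1", pos = 6e6, alt_count = 2, ref_count = 3),
    mut_row("A", chrom = "chrT2", pos = 5e6, alt_count = 20, ref_count = 40)))
  segs <- as_segments(rbind(
    seg_fix("A", "chrT1", 1, 200e6, 2, 1),
    seg_fix("A", "chrT2", 1, 100e6, 0, 0)))
  samples <- as_samples(sample_row("A", purity = 0.7))
  ds <- structure(list(mutations = muts, segments = segs, samples = samples),
                  class = "wex_cohort")
  calls <- clonality_calls(ds)
  expect_equal(nrow(calls), 1)
  excl <- attr(calls, "excluded")
  expect_equal(unname(excl["low_depth"]), 1L)
  expect_equal(unname(excl["homdel"]), 1L)
})
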