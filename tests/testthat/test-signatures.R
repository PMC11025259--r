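# Independent oracle: exhaustive grid over the 2-simplex at 0.01 resolution,
# minimizing squared reconstruction error of a two-signature mixture.
grid_refit_2sig <- function(counts, ref2) {
  alphas <- seq(0, 1, by = 0.01)
  total <- sum(counts)
  errs <- vapply(alphas, function(a) {
    recon <- total * (a * ref2[, 1] + (1 - a) * ref2[, 2])
    sum((counts - recon)^2)
  }, numeric(1))
  alphas[which.min(errs)]
}

test_that("noiseless two-signature mixtures are recovered within 0.02", {
  ref <- reference_signatures()
  counts <- round(2000 * (0.6 * ref[, "S1"] + 0.4 * ref[, "S13"]))
  fit <- refit_signatures(counts, ref)
  expect_equal(unname(fit$weights["S1"]), 0.60, tolerance = 0.02)
  expect_equal(unname(fit$weights["S13"]), 0.40, tolerance = 0.02)
  expect_gt(fit$reconstruction_cosine, 0.99)
  # grid oracle on the restricted two-signature problem agrees
  a_grid <- grid_refit_2sig(counts, ref[, c("S1", "S13")])
  expect_equal(unname(fit$weights["S1"]), a_grid, tolerance = 0.02)
})

test_that("refit exposures are nonnegative, unit-sum, and scale invariant", {
  ref <- reference_signatures()
  counts <- round(1500 * ref[, "S2"])
  fit <- refit_signatures(counts, ref)
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  expect_equal(unname(fit$weights["S2"]), 1, tolerance = 1e-6)
  fit10 <- refit_signatures(counts * 10, ref)
  expect_equal(fit10$weights, fit$weights, tolerance = 1e-8)
  expect_error(refit_signatures(numeric(96), ref), "all-zero")
})

test_that("positivity uses a strict 10% threshold", {
  w <- c(S1 = 0.11, S2 = 0.10, S3 = 0.0, S4 = 0.79)
  pos <- signature_positivity(w)
  expect_true(pos["S1"])
  expect_false(pos["S2"])   # boundary is strictly greater-than
  expect_false(pos["S3"])
})

test_that("NMF recovers planted signatures and honors rank bounds", {
  ref <- reference_signatures()
  truth <- ref[, c("S1", "S2", "S13")]
  V <- with_seed(99, {
    mix <- t(vapply(1:40, function(i) {
      w <- stats::rgamma(3, 1); w / sum(w)
    }, numeric(3)))
    vapply(1:40, function(i)
      as.numeric(stats::rpois(96, 2000 * truth %*% mix[i, ])), numeric(96))
  })
  fit <- extract_denovo_signatures(V, rank = 3, seed = 7, n_restarts = 3)
  sims <- vapply(seq_len(3), function(j)
    max(apply(truth, 2, function(t) {
      s <- fit$signatures[, j]
      sum(s * t) / sqrt(sum(s^2) * sum(t^2))
    })), numeric(1))
  expect_true(all(sims >= 0.95))
  expect_error(extract_denovo_signatures(V, rank = 50), "rank")
  expect_error(extract_denovo_signatures(-V, rank = 2), "nonnegative")
})

test_that("rank-1 NMF on identical spectra returns the common profile", {
  ref <- reference_signatures()
  v <- 1000 * ref[, "S6"]
  V <- cbind(v, v, v, v)
  fit <- extract_denovo_signatures(V, rank = 1, seed = 3, n_restarts = 2)
  cs <- sum(fit$signatures[, 1] * ref[, "S6"]) /
    sqrt(sum(fit$signatures[, 1]^2) * sum(ref[, "S6"]^2))
  expect_gt(cs, 0.9999)
})

test_that("longer NMF optimization never worsens the objective", {
  ref <- reference_signatures()
  V <- with_seed(4, vapply(1:10, function(i)
    as.numeric(stats::rpois(96, 500 * ref[, sample(30, 1)])), numeric(96)))
  short <- extract_denovo_signatures(V, 2, seed = 5, n_restarts = 1,
                                     max_iter = 20)
  long <- extract_denovo_signatures(V, 2, seed = 5, n_restarts = 1,
                                    max_iter = 500)
  expect_lte(long$objective, short$objective + 1e-8)
})

test_that("matching assigns exact copies and rejects unrelated profiles", {
  ref <- reference_signatures()
  m <- match_signatures(ref[, "S2", drop = FALSE], ref)
  expect_equal(m$match, "S2")
  expect_equal(m$cosine, 1, tolerance = 1e-12)
  flat <- matrix(rep(1 / 96, 96), ncol = 1,
                 dimnames = list(rownames(ref), "flat"))
  # direct-cosine oracle: the flat profile is closest to the near-flat S3,
  # so drop S3 from the catalog to probe the unassigned path
  ref_nos3 <- ref[, colnames(ref) != "S3"]
  best <- max(apply(ref_nos3, 2, function(r)
    sum(r * flat) / sqrt(sum(r^2) * sum(flat^2))))
  m2 <- match_signatures(flat, ref_nos3, min_cosine = 0.8)
  if (best < 0.8) expect_equal(m2$match, "unassigned")
  expect_equal(m2$cosine, best, tolerance = 1e-12)
  # a seeded sparse novel profile is unassigned against the full catalog
  nov <- matrix(novel_signature_profile(seed = 11), ncol = 1,
                dimnames = list(rownames(ref), "novel"))
  expect_equal(match_signatures(nov, ref, min_cosine = 0.8)$match,
               "unassigned")
  bad <- ref[, 1:2]; rownames(bad) <- rev(rownames(bad))
  expect_error(match_signatures(bad, ref), "96-bin order")
})

test_that("rank survey reports errors and stability for each rank", {
  ref <- reference_signatures()
  V <- with_seed(21, vapply(1:12, function(i)
    as.numeric(stats::rpois(96, 800 * ref[, c("S1", "S2")[1 + i %% 2]])),
    numeric(96)))
  sv <- nmf_rank_survey(V, ranks = 2:3, seed = 1, n_restarts = 2)
  expect_equal(sv$rank, 2:3)
  expect_true(all(sv$rel_error >= 0 & sv$rel_error < 1))
  expect_true(all(sv$stability > 0 & sv$stability <= 1 + 1e-9))
})
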