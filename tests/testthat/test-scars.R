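# All scar tests run on the synthetic two-chromosome test genome:
# chrT1 200 Mb (centromere 90-95 Mb), chrT2 100 Mb (centromere 45-50 Mb).

test_that("smoothing removes sub-3 Mb segments and merges identical flanks", {
  segs <- rbind(seg_fix(start = 1, end = 20e6, cn_total = 2, cn_minor = 1),
                seg_fix(start = 20e6 + 1, end = 22e6, cn_total = 3, cn_minor = 1),
                seg_fix(start = 22e6 + 1, end = 50e6, cn_total = 2, cn_minor = 1))
  out <- pp(segs)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 1)
  expect_equal(out$end, 50e6)
  expect_equal(out$cn_total, 2)
})

test_that("preprocessing is the identity when nothing is small or mergeable", {
  segs <- rbind(seg_fix(start = 1, end = 40e6, cn_total = 2, cn_minor = 1),
                seg_fix(start = 40e6 + 1, end = 89e6, cn_total = 3, cn_minor = 1))
  out <- pp(segs)
  expect_equal(out$start, c(1, 40e6 + 1))
  expect_equal(out$cn_total, c(2, 3))
})

test_that("segments spanning the centromere are split into arm-local parts", {
  out <- pp(seg_fix(start = 1, end = 200e6, cn_total = 2, cn_minor = 1))
  expect_equal(nrow(out), 2)
  expect_equal(out$arm, c("p", "q"))
  expect_equal(out$end[1], 90e6 - 1)
  expect_equal(out$start[2], 95e6 + 1)
  expect_equal(out$cn_total, c(2, 2))
  expect_error(pp(seg_fix(start = 1, end = 300e6)), "chromosome length")
})

test_that("LOH counts >15 Mb minor-zero segments, excluding whole-chromosome", {
  g <- test_genome()
  # 20 Mb (1,0) inside a chromosome otherwise diploid
  inner <- pp(rbind(
    seg_fix(start = 1, end = 30e6),
    seg_fix(start = 30e6 + 1, end = 50e6, cn_total = 1, cn_minor = 0),
    seg_fix(start = 50e6 + 1, end = 89e6)))
  expect_equal(count_hrd_loh(inner, g), 1L)
  # whole-chromosome LOH is excluded
  whole <- pp(seg_fix(start = 1, end = 200e6, cn_total = 1, cn_minor = 0))
  expect_equal(count_hrd_loh(whole, g), 0L)
  # 14 Mb misses the length rule
  short <- pp(rbind(
    seg_fix(start = 1, end = 30e6),
    seg_fix(start = 30e6 + 1, end = 44e6, cn_total = 1, cn_minor = 0),
    seg_fix(start = 44e6 + 1, end = 89e6)))
  expect_equal(count_hrd_loh(short, g), 0L)
})

test_that("TAI requires imbalance, telomere contact, and minimum size", {
  g <- test_genome()
  telomeric <- pp(rbind(
    seg_fix(start = 1, end = 30e6, cn_total = 3, cn_minor = 1),
    seg_fix(start = 30e6 + 1, end = 89e6)))
  expect_equal(count_tai(telomeric, g), 1L)
  # (2,1) is major 1 / minor 1: balanced
  balanced <- pp(rbind(seg_fix(start = 1, end = 30e6, cn_total = 2, cn_minor = 1),
                       seg_fix(start = 30e6 + 1, end = 89e6, cn_total = 4,
                               cn_minor = 2)))
  expect_equal(count_tai(balanced, g), 0L)
  interstitial <- pp(rbind(
    seg_fix(start = 1, end = 30e6),
    seg_fix(start = 30e6 + 1, end = 60e6, cn_total = 3, cn_minor = 1),
    seg_fix(start = 60e6 + 1, end = 89e6)))
  expect_equal(count_tai(interstitial, g), 0L)
  # q-arm telomere contact also counts
  q_tel <- pp(rbind(seg_fix(start = 95e6 + 1, end = 170e6),
                    seg_fix(start = 170e6 + 1, end = 200e6, cn_total = 3,
                            cn_minor = 1)))
  expect_equal(count_tai(q_tel, g), 1L)
})

test_that("LST counts transitions between >=10 Mb neighbors within an arm", {
  g <- test_genome()
  two <- pp(rbind(seg_fix(start = 1, end = 20e6),
                  seg_fix(start = 20e6 + 1, end = 35e6, cn_total = 3,
                          cn_minor = 1),
                  seg_fix(start = 35e6 + 1, end = 89e6)))
  expect_equal(count_lst(two, g), 2L)
  uniform <- pp(seg_fix(start = 1, end = 89e6))
  expect_equal(count_lst(uniform, g), 0L)
  # 8 Mb side disqualifies its breakpoint
  small_side <- pp(rbind(seg_fix(start = 1, end = 8e6),
                         seg_fix(start = 8e6 + 1, end = 35e6, cn_total = 3,
                                 cn_minor = 1),
                         seg_fix(start = 35e6 + 1, end = 89e6)))
  expect_equal(count_lst(small_side, g), 1L)
})

test_that("HRD score sums the three components with an inclusive 42 cutoff", {
  s <- hrd_score(10, 15, 20)
  expect_equal(s$hrd_score, 45L)
  expect_true(s$hrd_high)
  expect_false(hrd_score(0, 0, 0)$hrd_high)
  boundary <- hrd_score(14, 14, 14)
  expect_equal(boundary$hrd_score, 42L)
  expect_true(boundary$hrd_high)
  expect_false(hrd_score(14, 14, 13)$hrd_high)
  expect_error(hrd_score(-1, 0, 0), "nonnegative")
})

test_that("a fully diploid heterozygous genome scores zero everywhere", {
  g <- test_genome()
  segs <- as_segments(rbind(seg_fix(chrom = "chrT1", start = 1, end = 200e6),
                            seg_fix(chrom = "chrT2", start = 1, end = 100e6)))
  s <- scar_scores(segs, g)
  expect_equal(c(s$n_loh, s$n_tai, s$n_lst), c(0L, 0L, 0L))
  expect_false(s$hrd_high)
})

test_that("scores are invariant to splitting segments into abutting pieces", {
  sim <- small_sim()
  genome <- load_hg19_genome()
  sid <- sim$dataset$samples$sample_id[2]
  segs <- sim$dataset$segments[sim$dataset$segments$sample_id == sid, ]
  base <- scar_scores(segs, genome, sample_id = sid)
  split_segs <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    if (s$end - s$start > 2e6 && i %% 2 == 0) {
      mid <- floor((s$start + s$end) / 2)
      a <- s; a$end <- mid
      b <- s; b$start <- mid + 1
      rbind(a, b)
    } else s
  }))
  resplit <- scar_scores(as_segments(split_segs), genome, sample_id = sid)
  expect_equal(resplit$hrd_score, base$hrd_score)
  expect_equal(resplit$n_loh, base$n_loh)
  expect_equal(resplit$n_tai, base$n_tai)
  expect_equal(resplit$n_lst, base$n_lst)
})

test_that("cohort scoring recovers the generator's injected event counts", {
  sim <- small_sim()
  sc <- cohort_scar_scores(sim$dataset)
  truth <- sim$truth$samples
  expect_equal(sc$n_loh, truth$n_loh)
  expect_equal(sc$n_tai, truth$n_tai)
  expect_equal(sc$n_lst, truth$n_lst)
  expect_equal(sc$hrd_high, truth$hrd_score >= 42)
})
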