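toy_kb <- function() {
  df <- data.frame(
    gene = c("PIK3CA", "ERBB2", "PTEN", "BRCA1"),
    alteration_type = c("mutation", "amplification", "deletion", "mutation"),
    variant_filter = c("H1047R,E545K", "", "", ""),
    oncokb_loe = c("1", "1", "4", "1"),
    escat = c("I", "I", "II", "I"),
    stringsAsFactors = FALSE)
  path <- write_tsv_tmp(df)
  read_knowledge_base(path)
}

neutral_calls <- function(sid, genes = c("PIK3CA", "ERBB2", "PTEN", "BRCA1")) {
  data.frame(sample_id = sid, gene = genes, log2r = 0, call = "neutral",
             missing = FALSE, stringsAsFactors = FALSE)
}

test_that("knowledge-base validation enforces the entry contract", {
  kb <- toy_kb()
  expect_s3_class(kb, "wex_kb")
  bad <- as.data.frame(kb); bad$alteration_type[1] <- "fusion"
  expect_error(read_knowledge_base(write_tsv_tmp(bad)), "fusion")
  bad2 <- as.data.frame(kb); bad2$oncokb_loe[3] <- "none"; bad2$escat[3] <- "none"
  expect_error(read_knowledge_base(write_tsv_tmp(bad2)), "at least one")
  expect_s3_class(load_default_knowledge_base(), "wex_kb")
})

test_that("hotspot mutations and CNA calls match their KB entries", {
  kb <- toy_kb()
  mut <- as_mutations(mut_row(gene = "PIK3CA", variant_class = "missense",
                              protein_change = "H1047R"))
  aga <- annotate_aga(mut, neutral_calls("S1"), kb)
  expect_equal(nrow(aga), 1)
  expect_equal(aga$oncokb_loe, "1")
  expect_equal(aga$escat, "I")
  # amplification entry matches only call == amplification
  calls <- neutral_calls("S1")
  calls$call[calls$gene == "ERBB2"] <- "amplification"
  aga2 <- annotate_aga(mut[0, ], calls, kb)
  expect_equal(aga2$gene, "ERBB2")
  calls$call[calls$gene == "ERBB2"] <- "gain"
  expect_equal(nrow(annotate_aga(mut[0, ], calls, kb)), 0)
})

test_that("silent variants and non-hotspot changes never match a filter", {
  kb <- toy_kb()
  silent <- as_mutations(mut_row(gene = "PIK3CA", variant_class = "silent",
                                 protein_change = "H1047R"))
  expect_equal(nrow(annotate_aga(silent, neutral_calls("S1"), kb)), 0)
  off_hotspot <- as_mutations(mut_row(gene = "PIK3CA",
                                      variant_class = "missense",
                                      protein_change = "R88Q"))
  expect_equal(nrow(annotate_aga(off_hotspot, neutral_calls("S1"), kb)), 0)
  # entries without a filter accept any non-silent variant
  any_brca <- as_mutations(mut_row(gene = "BRCA1", variant_class = "nonsense"))
  expect_equal(annotate_aga(any_brca, neutral_calls("S1"), kb)$gene, "BRCA1")
})

test_that("annotation is deterministic and order-independent", {
  kb <- toy_kb()
  mut <- as_mutations(rbind(
    mut_row(pos = 1, gene = "PIK3CA", variant_class = "missense",
            protein_change = "E545K"),
    mut_row(pos = 2, gene = "BRCA1", variant_class = "missense")))
  a <- annotate_aga(mut, neutral_calls("S1"), kb)
  b <- annotate_aga(mut[2:1, ], neutral_calls("S1"), kb)
  expect_equal(a[order(a$gene), ], b[order(b$gene), ], ignore_attr = TRUE)
})

test_that("summary flags respect the evidence hierarchy and group percentages", {
  samples <- as_samples(rbind(sample_row("A"), sample_row("B"),
                              sample_row("C"), sample_row("D")))
  ann <- data.frame(
    sample_id = c("A", "A", "B", "C"),
    gene = c("PIK3CA", "PTEN", "ERBB2", "PTEN"),
    alteration_type = c("mutation", "deletion", "amplification", "deletion"),
    detail = "x",
    oncokb_loe = c("1", "4", "1", "4"),
    escat = c("I", "II", "I", "II"), stringsAsFactors = FALSE)
  s <- summarize_actionability(ann, samples)
  a <- s$per_sample[s$per_sample$sample_id == "A", ]
  expect_true(a$has_any_aga && a$has_loe12 && a$has_loe34)
  expect_equal(a$n_agas, 2)
  d <- s$per_sample[s$per_sample$sample_id == "D", ]
  expect_false(d$has_any_aga || d$has_loe12 || d$has_loe34 || d$has_escat_I_II)
  # flag hierarchy: any LOE flag implies has_any_aga
  expect_true(all(!(s$per_sample$has_loe12 | s$per_sample$has_loe34) |
                    s$per_sample$has_any_aga))
  expect_equal(s$per_group$pct_any_aga, 75)
  expect_equal(s$per_group$pct_multi_aga, 25)
})

test_that("pairwise exclusivity builds the 2x2 table and Fisher result", {
  samples <- as_samples(do.call(rbind, lapply(
    sprintf("S%02d", 1:20), function(s) sample_row(s))))
  ann <- data.frame(
    sample_id = sprintf("S%02d", 1:20),
    gene = rep(c("PIK3CA", "ERBB2"), each = 10),
    alteration_type = "mutation", detail = "x",
    oncokb_loe = "1", escat = "I", stringsAsFactors = FALSE)
  res <- pairwise_exclusivity(ann, samples, "PIK3CA", "ERBB2")
  expect_equal(as.numeric(res$table), c(0, 10, 10, 0))
  expect_lt(res$fisher$odds_ratio, 0.1)
  expect_error(pairwise_exclusivity(ann, samples[0, ], "PIK3CA", "ERBB2"),
               "no samples")
})

test_that("independent alteration flags give an odds ratio near 1", {
  # simulation oracle: two independent 50% flags over many samples
  with_seed(13, {
    n <- 10000
    sids <- sprintf("S%05d", 1:n)
    samples <- as_samples(data.frame(
      sample_id = sids, group = "IBC", subtype = "TN", age = 50,
      purity = 0.7, ploidy = 2, panel_size_mb = 38,
      stringsAsFactors = FALSE))
    a <- stats::runif(n) < 0.5
    b <- stats::runif(n) < 0.5
    ann <- rbind(
      data.frame(sample_id = sids[a], gene = "PIK3CA",
                 alteration_type = "mutation", detail = "x",
                 oncokb_loe = "1", escat = "I", stringsAsFactors = FALSE),
      data.frame(sample_id = sids[b], gene = "ERBB2",
                 alteration_type = "amplification", detail = "x",
                 oncokb_loe = "1", escat = "I", stringsAsFactors = FALSE))
    res <- pairwise_exclusivity(ann, samples, "PIK3CA", "ERBB2")
    expect_equal(res$fisher$odds_ratio, 1, tolerance = 0.15)
  })
})
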