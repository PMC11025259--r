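# Mutation burden and class accounting.

CODING_CLASSES_FOR_TMB <- c("missense", "nonsense", "silent")

#' Tumor mutational burden of one sample
#'
#' TMB is the number of somatic coding mutations — missense, nonsense,
#' silent, and indels — divided by the size of the sequenced territory in
#' megabases. A sample is flagged high-TMB when TMB exceeds 10 mutations/Mb.
#'
#' @param mutations mutation data.frame for one sample.
#' @param panel_size_mb sequenced territory in Mb; must be > 0.
#' @param high_cut high-TMB threshold in mutations/Mb (strict `>`).
#' @return list with `tmb` (mutations/Mb), `n_coding`, `high_tmb`.
#' @export
compute_tmb <- function(mutations, panel_size_mb, high_cut = 10) {
  assert_that(is.numeric(panel_size_mb) && panel_size_mb > 0,
              "panel_size_mb must be a positive number")
  n <- sum(mutations$variant_class %in% CODING_CLASSES_FOR_TMB |
             mutations$variant_type == "indel")
  tmb <- n / panel_size_mb
  list(tmb = tmb, n_coding = n, high_tmb = tmb > high_cut)
}

#' Per-sample and per-group mutation class accounting
#'
#' Counts mutations, SNVs, indels, and variant classes per sample, and
#' derives the class fractions the cohort comparison uses: non-silent
#' fraction among all mutations, SNV fraction, and missense/nonsense
#' fractions among non-silent SNVs. Fractions of empty samples are `NA`.
#'
#' @param dataset `wex_cohort` object.
#' @return list with `per_sample` (one row per sample, including samples with
#'   zero mutations) and `per_group` (aggregate class fractions).
#' @export
burden_summary <- function(dataset) {
  mut <- dataset$mutations
  samples <- dataset$samples
  per_sample <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    m <- mut[mut$sample_id == sid, , drop = FALSE]
    n <- nrow(m)
    n_snv <- sum(m$variant_type == "SNV")
    n_silent <- sum(m$variant_class == "silent")
    nonsilent_snv <- m$variant_type == "SNV" & m$variant_class != "silent"
    meta <- samples[samples$sample_id == sid, ]
    tmb <- compute_tmb(m, meta$panel_size_mb)
    data.frame(
      sample_id = sid, group = meta$group, subtype = meta$subtype,
      n_mutations = n, n_snv = n_snv, n_indel = n - n_snv,
      n_silent = n_silent, n_nonsilent = n - n_silent,
      n_missense = sum(m$variant_class == "missense"),
      n_nonsense = sum(m$variant_class == "nonsense"),
      frac_snv = if (n > 0) n_snv / n else NA_real_,
      frac_nonsilent = if (n > 0) (n - n_silent) / n else NA_real_,
      frac_missense_of_nonsilent_snv =
        if (sum(nonsilent_snv) > 0)
          sum(nonsilent_snv & m$variant_class == "missense") / sum(nonsilent_snv)
        else NA_real_,
      frac_nonsense_of_nonsilent_snv =
        if (sum(nonsilent_snv) > 0)
          sum(nonsilent_snv & m$variant_class == "nonsense") / sum(nonsilent_snv)
        else NA_real_,
      tmb_per_mb = tmb$tmb, high_tmb = tmb$high_tmb,
      stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  per_group <- do.call(rbind, lapply(unique(samples$group), function(g) {
    ps <- per_sample[per_sample$group == g, ]
    data.frame(
      group = g, n_samples = nrow(ps),
      n_mutations = sum(ps$n_mutations),
      frac_snv = sum(ps$n_snv) / max(sum(ps$n_mutations), 1),
      frac_nonsilent = sum(ps$n_nonsilent) / max(sum(ps$n_mutations), 1),
      median_mutations = stats::median(ps$n_mutations),
      median_tmb = stats::median(ps$tmb_per_mb),
      stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, per_group = per_group)
}

#' Per-gene mutated-sample fractions by group
#'
#' A sample counts once per gene no matter how many hits it carries. The
#' output feeds the per-gene Fisher/FDR comparison layer.
#'
#' @param dataset `wex_cohort` object.
#' @param gene_list genes to tabulate; defaults to all genes observed in the
#'   cohort's mutation table.
#' @return data.frame with columns `gene`, and per group `n_mutated_<group>`
#'   and `freq_<group>`.
#' @export
gene_mutation_frequencies <- function(dataset, gene_list = NULL) {
  mut <- dataset$mutations
  samples <- dataset$samples
  if (is.null(gene_list)) gene_list <- sort(unique(mut$gene))
  assert_that(length(gene_list) > 0, "gene_list must be non-empty")
  groups <- unique(samples$group)
  hit <- unique(mut[, c("sample_id", "gene")])
  out <- data.frame(gene = gene_list, stringsAsFactors = FALSE)
  for (g in groups) {
    sids <- samples$sample_id[samples$group == g]
    hg <- hit[hit$sample_id %in% sids, ]
    counts <- table(factor(hg$gene, levels = gene_list))
    out[[paste0("n_mutated_", g)]] <- as.integer(counts)
    out[[paste0("n_samples_", g)]] <- length(sids)
    out[[paste0("freq_", g)]] <- as.numeric(counts) / max(length(sids), 1)
  }
  out
}

#' Whole-cohort mutation accounting totals
#'
#' The headline counting statistics of a mutation list: total mutations,
#' distinct mutated genes, per-sample median (and range), SNV and non-silent
#' percentages, and the mutated-sample fraction of selected genes.
#'
#' @param mutations mutation data.frame (whole cohort or one group).
#' @param n_samples number of samples the table covers (needed because
#'   samples with zero mutations do not appear in the table).
#' @param genes genes whose mutated-sample fraction to report.
#' @return named list of totals.
#' @export
cohort_mutation_totals <- function(mutations, n_samples,
                                   genes = c("TP53", "PIK3CA")) {
  per_sample <- table(factor(mutations$sample_id,
                             levels = unique(mutations$sample_id)))
  counts <- as.numeric(per_sample)
  if (n_samples > length(counts)) counts <- c(counts, rep(0, n_samples - length(counts)))
  gene_frac <- vapply(genes, function(g) {
    length(unique(mutations$sample_id[mutations$gene == g])) / n_samples
  }, numeric(1))
  list(
    n_mutations = nrow(mutations),
    n_genes = length(unique(mutations$gene)),
    median_mutations_per_sample = stats::median(counts),
    min_mutations_per_sample = min(counts),
    max_mutations_per_sample = max(counts),
    pct_snv = 100 * mean(mutations$variant_type == "SNV"),
    pct_nonsilent = 100 * mean(mutations$variant_class != "silent"),
    gene_mutated_fraction = gene_frac)
}

#' Tag mutations that fall in the bundled driver-gene list
#' @param mutations mutation data.frame.
#' @return logical vector, one element per mutation row.
#' @export
tag_driver_genes <- function(mutations) {
  drivers <- read_wex_tsv(wex_extdata("breast_driver_genes.tsv"))$gene
  mutations$gene %in% drivers
}
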