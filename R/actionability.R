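# Actionable genomic alteration (AGA) annotation against a tiered knowledge
# base carrying OncoKB-style levels of evidence (1-4) and ESCAT tiers
# (I-II), and cohort-level actionability summaries.

KB_ALTERATION_TYPES <- c("mutation", "amplification", "deletion")
ONCOKB_LEVELS <- c("1", "2", "3", "4", "none")
ESCAT_LEVELS <- c("I", "II", "none")

#' Read an actionability knowledge base
#'
#' @param path TSV with columns `gene`, `alteration_type`
#'   (mutation/amplification/deletion), `variant_filter` (comma-separated
#'   protein changes; empty = any non-silent variant), `oncokb_loe`
#'   (1/2/3/4/none), `escat` (I/II/none).
#' @return validated data.frame of class `wex_kb`.
#' @export
read_knowledge_base <- function(path) {
  kb <- read_wex_tsv(path)
  require_columns(kb, c("gene", "alteration_type", "variant_filter",
                        "oncokb_loe", "escat"), "knowledge base")
  kb$gene <- as.character(kb$gene)
  kb$alteration_type <- as.character(kb$alteration_type)
  kb$variant_filter <- as.character(kb$variant_filter)
  kb$variant_filter[is.na(kb$variant_filter)] <- ""
  kb$oncokb_loe <- as.character(kb$oncokb_loe)
  kb$escat <- as.character(kb$escat)
  bad <- setdiff(unique(kb$alteration_type), KB_ALTERATION_TYPES)
  assert_that(length(bad) == 0,
              sprintf("unknown alteration_type '%s'; allowed: %s",
                      paste(bad, collapse = ", "),
                      paste(KB_ALTERATION_TYPES, collapse = ", ")))
  assert_that(all(kb$oncokb_loe %in% ONCOKB_LEVELS),
              "oncokb_loe must be one of 1, 2, 3, 4, none")
  assert_that(all(kb$escat %in% ESCAT_LEVELS),
              "escat must be one of I, II, none")
  assert_that(all(kb$oncokb_loe != "none" | kb$escat != "none"),
              "each KB entry needs at least one of oncokb_loe/escat")
  key <- paste(kb$gene, kb$alteration_type, kb$variant_filter)
  assert_that(!anyDuplicated(key), "duplicate knowledge-base entry")
  class(kb) <- c("wex_kb", "data.frame")
  kb
}

#' The bundled mini knowledge base
#'
#' A frozen snapshot covering the alteration classes most relevant in breast
#' cancer: ERBB2 amplification and PIK3CA hotspot mutations (OncoKB level 1
#' / ESCAT I), BRCA1/2 mutation or deletion, PTEN deletion and AKT1 E17K and
#' ESR1 mutations (ESCAT II). User-supplied KBs in the same format replace
#' it.
#'
#' @return `wex_kb` data.frame.
#' @export
load_default_knowledge_base <- function() {
  read_knowledge_base(wex_extdata("mini_actionability_kb.tsv"))
}

match_mutation_entry <- function(mut, entry) {
  if (mut$gene != entry$gene) return(FALSE)
  if (mut$variant_class == "silent") return(FALSE)
  if (nzchar(entry$variant_filter)) {
    hotspots <- trimws(strsplit(entry$variant_filter, ",")[[1]])
    pc <- mut$protein_change %||% NA_character_
    if (is.na(pc) || !pc %in% hotspots) return(FALSE)
  }
  TRUE
}

#' Annotate one sample's alterations against the knowledge base
#'
#' Mutations match `mutation` entries on gene (and hotspot protein change
#' when the entry carries a filter; silent variants never match). Gene CNA
#' calls match `amplification`/`deletion` entries on gene and call. Each
#' match carries both tier labels.
#'
#' @param mutations mutation data.frame of one sample (optionally with a
#'   `protein_change` column).
#' @param cna_calls gene CNA call data.frame of the same sample.
#' @param kb `wex_kb` knowledge base.
#' @return data.frame of matched AGAs: `sample_id`, `gene`,
#'   `alteration_type`, `detail`, `oncokb_loe`, `escat`.
#' @export
annotate_aga <- function(mutations, cna_calls, kb = load_default_knowledge_base()) {
  sid <- unique(c(mutations$sample_id, cna_calls$sample_id))
  sid <- sid[!is.na(sid)][1] %||% NA_character_
  hits <- list()
  for (e in seq_len(nrow(kb))) {
    entry <- kb[e, ]
    if (entry$alteration_type == "mutation") {
      for (i in seq_len(nrow(mutations))) {
        if (match_mutation_entry(mutations[i, ], entry)) {
          hits[[length(hits) + 1]] <- data.frame(
            sample_id = sid, gene = entry$gene, alteration_type = "mutation",
            detail = mutations$protein_change[i] %||% mutations$variant_class[i],
            oncokb_loe = entry$oncokb_loe, escat = entry$escat,
            stringsAsFactors = FALSE)
        }
      }
    } else {
      want <- entry$alteration_type   # "amplification" or "deletion"
      m <- cna_calls$gene == entry$gene & cna_calls$call == want
      if (any(m)) {
        hits[[length(hits) + 1]] <- data.frame(
          sample_id = sid, gene = entry$gene, alteration_type = want,
          detail = want, oncokb_loe = entry$oncokb_loe, escat = entry$escat,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      alteration_type = character(0), detail = character(0),
                      oncokb_loe = character(0), escat = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, hits))
}

#' Annotate every sample in a cohort
#' @param dataset `wex_cohort` object.
#' @param cna_calls stacked gene CNA calls (from [cohort_cna_calls()]).
#' @param kb knowledge base.
#' @return stacked AGA data.frame.
#' @export
cohort_aga_annotations <- function(dataset, cna_calls,
                                   kb = load_default_knowledge_base()) {
  do.call(rbind, lapply(dataset$samples$sample_id, function(sid) {
    a <- annotate_aga(
      dataset$mutations[dataset$mutations$sample_id == sid, , drop = FALSE],
      cna_calls[cna_calls$sample_id == sid, , drop = FALSE], kb)
    if (nrow(a)) a$sample_id <- sid
    a
  }))
}

#' Summarize actionability per sample and per group
#'
#' Per sample: whether any AGA exists, whether an OncoKB LOE 1-2 or LOE 3-4
#' AGA exists, whether an ESCAT I-II AGA exists, and the number of AGAs.
#' Per group: the percentage of samples with each flag and with two or more
#' AGAs.
#'
#' @param annotations stacked AGA data.frame.
#' @param samples `wex_samples` data.frame (every sample appears in the
#'   summary, also those with zero matches).
#' @return list with `per_sample` and `per_group` data.frames.
#' @export
summarize_actionability <- function(annotations, samples) {
  per_sample <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    a <- annotations[annotations$sample_id == sid, , drop = FALSE]
    data.frame(
      sample_id = sid, group = samples$group[samples$sample_id == sid],
      n_agas = nrow(a),
      has_any_aga = nrow(a) > 0,
      has_loe12 = any(a$oncokb_loe %in% c("1", "2")),
      has_loe34 = any(a$oncokb_loe %in% c("3", "4")),
      has_escat_I_II = any(a$escat %in% c("I", "II")),
      stringsAsFactors = FALSE)
  }))
  per_group <- do.call(rbind, lapply(unique(samples$group), function(g) {
    ps <- per_sample[per_sample$group == g, ]
    data.frame(group = g, n_samples = nrow(ps),
               pct_any_aga = 100 * mean(ps$has_any_aga),
               pct_loe12 = 100 * mean(ps$has_loe12),
               pct_loe34 = 100 * mean(ps$has_loe34),
               pct_escat_I_II = 100 * mean(ps$has_escat_I_II),
               pct_multi_aga = 100 * mean(ps$n_agas >= 2),
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, per_group = per_group)
}

#' Mutual-exclusivity cross-tabulation of two actionable genes
#'
#' @param annotations stacked AGA data.frame.
#' @param samples `wex_samples` data.frame.
#' @param gene_a,gene_b gene symbols.
#' @return list with the 2x2 `table` (A-altered x B-altered) and the
#'   [fisher_exact()] result.
#' @export
pairwise_exclusivity <- function(annotations, samples, gene_a, gene_b) {
  assert_that(nrow(samples) > 0, "no samples in cohort")
  a_alt <- samples$sample_id %in% annotations$sample_id[annotations$gene == gene_a]
  b_alt <- samples$sample_id %in% annotations$sample_id[annotations$gene == gene_b]
  tab <- table(factor(a_alt, levels = c(TRUE, FALSE)),
               factor(b_alt, levels = c(TRUE, FALSE)),
               dnn = c(gene_a, gene_b))
  list(table = tab,
       fisher = fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}
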