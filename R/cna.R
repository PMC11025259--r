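# Gene-level copy-number alteration calls and cohort frequency profiles.

#' Default CNA call thresholds on the log2 ratio scale
#'
#' Gain above 0.2, amplification above 0.9, loss below -0.2, deletion below
#' -0.9, all strict; everything else neutral.
#'
#' @return named numeric vector with `gain`, `amplification`, `loss`,
#'   `deletion`.
#' @export
default_cna_thresholds <- function() {
  c(gain = 0.2, amplification = 0.9, loss = -0.2, deletion = -0.9)
}

cna_call_from_log2r <- function(log2r, thresholds) {
  ifelse(is.na(log2r), "neutral",
  ifelse(log2r > thresholds["amplification"], "amplification",
  ifelse(log2r > thresholds["gain"], "gain",
  ifelse(log2r < thresholds["deletion"], "deletion",
  ifelse(log2r < thresholds["loss"], "loss", "neutral")))))
}

segment_log2r <- function(seg) {
  if (!is.null(seg$log2r) && !all(is.na(seg$log2r))) {
    l <- seg$log2r
  } else {
    l <- rep(NA_real_, nrow(seg))
  }
  # derive from total copy number where not supplied; floor CN at 0.25
  # copies so homozygous deletions map to a finite, strongly negative ratio
  miss <- is.na(l)
  l[miss] <- log2(pmax(seg$cn_total[miss], 0.25) / 2)
  l
}

#' Call gene-level copy-number alterations for one sample
#'
#' Each gene gets the log2 ratio of the segment overlapping it the most
#' (ties broken toward the larger absolute ratio), thresholded into
#' amplification / gain / neutral / loss / deletion. Genes with no
#' overlapping segment are neutral with `missing = TRUE`. When the segment
#' table has no `log2r` column the ratio is derived as
#' `log2(cn_total / 2)`.
#'
#' @param segments segment data.frame of one sample.
#' @param gene_model data.frame from [read_gene_model()].
#' @param thresholds named vector as from [default_cna_thresholds()].
#' @param sample_id sample identifier carried into the output.
#' @return data.frame with columns `sample_id`, `gene`, `log2r`, `call`,
#'   `missing`; exactly one row per gene in the model.
#' @export
gene_cna_call <- function(segments, gene_model,
                          thresholds = default_cna_thresholds(),
                          sample_id = NA_character_) {
  l2r <- segment_log2r(segments)
  out <- lapply(seq_len(nrow(gene_model)), function(i) {
    g <- gene_model[i, ]
    on_chrom <- which(segments$chrom == g$chrom)
    ov <- pmin(segments$end[on_chrom], g$end) -
      pmax(segments$start[on_chrom], g$start) + 1
    hit <- on_chrom[ov > 0]
    ov <- ov[ov > 0]
    if (length(hit) == 0) {
      return(data.frame(sample_id = sample_id, gene = g$gene,
                        log2r = NA_real_, call = "neutral", missing = TRUE,
                        stringsAsFactors = FALSE))
    }
    best <- hit[ov == max(ov)]
    if (length(best) > 1) best <- best[which.max(abs(l2r[best]))]
    val <- l2r[best]
    data.frame(sample_id = sample_id, gene = g$gene, log2r = val,
               call = unname(cna_call_from_log2r(val, thresholds)),
               missing = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene CNA calls for every sample in a cohort
#' @param dataset `wex_cohort` object.
#' @param gene_model gene model data.frame.
#' @param thresholds CNA thresholds.
#' @return data.frame stacking [gene_cna_call()] over samples.
#' @export
cohort_cna_calls <- function(dataset, gene_model = load_default_gene_model(),
                             thresholds = default_cna_thresholds()) {
  do.call(rbind, lapply(dataset$samples$sample_id, function(sid)
    gene_cna_call(
      dataset$segments[dataset$segments$sample_id == sid, , drop = FALSE],
      gene_model, thresholds, sample_id = sid)))
}

#' Per-gene alteration frequencies by group
#'
#' Fraction of samples per group carrying a gain-or-amplification and a
#' loss-or-deletion call per gene, on the 0-100% scale. Feeds the per-gene
#' Fisher/FDR comparison.
#'
#' @param calls stacked gene CNA calls (from [cohort_cna_calls()]).
#' @param samples `wex_samples` data.frame supplying the group labels.
#' @return data.frame with, per group, `pct_gained_<group>` and
#'   `pct_lost_<group>` plus the underlying counts.
#' @export
cna_frequency_profile <- function(calls, samples) {
  calls$group <- samples$group[match(calls$sample_id, samples$sample_id)]
  genes <- unique(calls$gene)
  groups <- unique(samples$group)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (g in groups) {
    cg <- calls[calls$group == g, ]
    n <- length(unique(cg$sample_id))
    gained <- tapply(cg$call %in% c("gain", "amplification"), cg$gene, sum)
    lost <- tapply(cg$call %in% c("loss", "deletion"), cg$gene, sum)
    out[[paste0("n_gained_", g)]] <- as.integer(gained[genes])
    out[[paste0("n_lost_", g)]] <- as.integer(lost[genes])
    out[[paste0("n_samples_", g)]] <- n
    out[[paste0("pct_gained_", g)]] <- 100 * as.numeric(gained[genes]) / max(n, 1)
    out[[paste0("pct_lost_", g)]] <- 100 * as.numeric(lost[genes]) / max(n, 1)
  }
  out
}
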