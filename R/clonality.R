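#' @importFrom mclust Mclust mclustBIC
NULL

# Cancer cell fraction estimation, credible-interval clonal/subclonal
# classification, CCF clustering and the Shannon heterogeneity index.
#
# Model: a mutation at multiplicity m on a site of total copy number n_t in
# a tumor of purity p has expected VAF = CCF * p * m / (p * n_t + 2 (1 - p)).
# The VAF -> CCF transform is linear and monotone at fixed (p, n_t, m), so a
# credible interval on the VAF posterior maps directly onto the CCF scale.

ccf_denominator <- function(purity, cn_total) purity * cn_total + 2 * (1 - purity)

#' Estimate mutation multiplicity
#'
#' Rounds the purity- and copy-number-corrected allele fraction to the
#' nearest integer number of mutated copies, clamped to `[1, cn_total]`.
#'
#' @param vaf variant allele fraction in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @param cn_total total copy number at the site, `>= 1`.
#' @return integer multiplicity.
#' @export
estimate_multiplicity <- function(vaf, purity, cn_total) {
  assert_that(all(purity > 0 & purity <= 1), "purity must be in (0, 1]")
  assert_that(all(cn_total >= 1), "cn_total must be >= 1 (homozygous-deletion sites are excluded upstream)")
  m <- round(vaf / purity * ccf_denominator(purity, cn_total))
  as.integer(pmin(pmax(m, 1), cn_total))
}

#' Cancer cell fraction of a mutation
#'
#' @param vaf variant allele fraction.
#' @param purity tumor purity in `(0, 1]`.
#' @param cn_total total copy number, `>= 1`.
#' @param m multiplicity, `>= 1`.
#' @param cap_max reporting cap on the CCF (default 2).
#' @return numeric CCF.
#' @export
compute_ccf <- function(vaf, purity, cn_total, m, cap_max = 2) {
  ccf <- vaf * ccf_denominator(purity, cn_total) / (purity * m)
  pmin(ccf, cap_max)
}

#' Highest density interval of a Beta distribution
#'
#' The narrowest interval holding `level` posterior mass, found by
#' minimizing the interval width over the lower tail probability.
#'
#' @param a,b Beta shape parameters.
#' @param level credible level.
#' @return numeric `c(low, high)`.
#' @export
beta_hdi <- function(a, b, level = 0.95) {
  if (a <= 1 && b > 1) return(c(0, stats::qbeta(level, a, b)))
  if (b <= 1 && a > 1) return(c(stats::qbeta(1 - level, a, b), 1))
  if (a <= 1 && b <= 1) {  # flat or bimodal: fall back to central interval
    return(stats::qbeta(c((1 - level) / 2, (1 + level) / 2), a, b))
  }
  width <- function(p) stats::qbeta(p + level, a, b) - stats::qbeta(p, a, b)
  opt <- stats::optimize(width, c(0, 1 - level))
  c(stats::qbeta(opt$minimum, a, b), stats::qbeta(opt$minimum + level, a, b))
}

#' Credible interval of a mutation's CCF
#'
#' Posterior on the VAF is `Beta(alt + 1, ref + 1)` (uniform prior); its
#' highest density interval is mapped through the linear VAF-to-CCF
#' transform at fixed purity, copy number, and multiplicity.
#'
#' @param alt_count,ref_count supporting and reference read counts.
#' @param purity,cn_total,m as in [compute_ccf()].
#' @param level credible level (default 0.95).
#' @param min_depth minimum total depth; below it an error of class
#'   `wexscape_low_depth` is raised so callers can exclude and count.
#' @return numeric `c(low, high)` on the CCF scale.
#' @export
ccf_credible_interval <- function(alt_count, ref_count, purity, cn_total, m,
                                  level = 0.95, min_depth = 8) {
  if (alt_count + ref_count < min_depth)
    abort_wex(sprintf("depth %d below min_depth %d", alt_count + ref_count,
                      min_depth), "wexscape_low_depth")
  hdi <- beta_hdi(alt_count + 1, ref_count + 1, level)
  hdi * ccf_denominator(purity, cn_total) / (purity * m)
}

#' Classify a CCF credible interval as clonal or subclonal
#'
#' Clonal when CCF = 1 lies inside the interval. Intervals lying entirely
#' above 1 (an artifact of integer multiplicity rounding) are also called
#' Clonal by default; `strict = TRUE` restores the literal containment rule.
#'
#' @param interval numeric `c(low, high)` on the CCF scale.
#' @param strict logical; when TRUE only containment of 1 gives Clonal.
#' @return `"Clonal"` or `"Subclonal"`.
#' @export
classify_clonality <- function(interval, strict = FALSE) {
  low <- interval[1]; high <- interval[2]
  assert_that(low <= high, "interval low must be <= high")
  if (low <= 1 && 1 <= high) return("Clonal")
  if (!strict && low > 1) return("Clonal")
  "Subclonal"
}

# Total copy number at a position from the sample's segment profile;
# default 2 when no segment overlaps.
cn_at_position <- function(segments, chrom, pos) {
  hit <- segments$chrom == chrom & segments$start <= pos & segments$end >= pos
  if (!any(hit)) 2L else as.integer(segments$cn_total[which(hit)[1]])
}

#' Per-mutation clonality calls for a cohort
#'
#' Joins purity from the sample sheet and total copy number from the segment
#' profile, estimates multiplicity, computes the CCF with its credible
#' interval, and labels each mutation Clonal/Subclonal. Mutations on
#' homozygous-deletion sites or below `min_depth` are excluded; exclusion
#' counts are attached as the `excluded` attribute.
#'
#' @param dataset `wex_cohort` object.
#' @param level HDI credible level.
#' @param min_depth minimum read depth.
#' @param strict literal containment rule, see [classify_clonality()].
#' @return data.frame with one row per retained mutation: `sample_id`,
#'   `chrom`, `pos`, `gene`, `vaf`, `cn_total`, `m`, `ccf`, `hdi_low`,
#'   `hdi_high`, `label`.
#' @export
clonality_calls <- function(dataset, level = 0.95, min_depth = 8,
                            strict = FALSE) {
  mut <- dataset$mutations
  samples <- dataset$samples
  n_lowdepth <- 0L; n_homdel <- 0L
  rows <- vector("list", nrow(mut))
  for (i in seq_len(nrow(mut))) {
    m_i <- mut[i, ]
    meta <- samples[samples$sample_id == m_i$sample_id, ]
    depth <- m_i$alt_count + m_i$ref_count
    if (depth < min_depth) { n_lowdepth <- n_lowdepth + 1L; next }
    seg <- dataset$segments[dataset$segments$sample_id == m_i$sample_id, ,
                            drop = FALSE]
    cn <- cn_at_position(seg, m_i$chrom, m_i$pos)
    if (cn == 0) { n_homdel <- n_homdel + 1L; next }
    vaf <- m_i$alt_count / depth
    mult <- estimate_multiplicity(vaf, meta$purity, cn)
    ccf <- compute_ccf(vaf, meta$purity, cn, mult)
    hdi <- ccf_credible_interval(m_i$alt_count, m_i$ref_count, meta$purity,
                                 cn, mult, level = level,
                                 min_depth = min_depth)
    rows[[i]] <- data.frame(
      sample_id = m_i$sample_id, chrom = m_i$chrom, pos = m_i$pos,
      gene = m_i$gene, vaf = vaf, cn_total = cn, m = mult, ccf = ccf,
      hdi_low = hdi[1], hdi_high = hdi[2],
      label = classify_clonality(hdi, strict = strict),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  attr(out, "excluded") <- c(low_depth = n_lowdepth, homdel = n_homdel)
  out
}

#' Cluster one sample's CCFs and compute the Shannon heterogeneity index
#'
#' Fits 1-D Gaussian mixtures on the CCF values (copy-number-neutral
#' mutations only by default) for k = 1..`max_k` by EM, picks k by BIC,
#' drops clusters holding under 2% of mutations, renormalizes proportions,
#' and computes `H = -sum(p log p)` with the `H > 1` heterogeneity flag.
#' Values are sorted before fitting so the solution is invariant to input
#' order.
#'
#' @param calls clonality-call data.frame of one sample (from
#'   [clonality_calls()]).
#' @param max_k maximum number of clusters.
#' @param seed integer seed for the mixture fit.
#' @param min_mutations below this the sample is not assessable.
#' @param cn_neutral_only restrict to `cn_total == 2` sites (default TRUE).
#' @param min_cluster_prop clusters below this share are dropped.
#' @return list of class `wex_clusters` with `k`, `means`, `proportions`,
#'   `assignments` (in input row order, NA for excluded rows), `H`,
#'   `heterogeneous`, `assessable`.
#' @export
cluster_ccfs <- function(calls, max_k = 6, seed = 1, min_mutations = 10,
                         cn_neutral_only = TRUE, min_cluster_prop = 0.02) {
  use <- if (cn_neutral_only) calls$cn_total == 2 else rep(TRUE, nrow(calls))
  ccf <- calls$ccf[use]
  if (length(ccf) < min_mutations) {
    return(structure(list(sample_id = unique(calls$sample_id) %||% NA,
                          k = NA_integer_, means = numeric(0),
                          proportions = numeric(0),
                          assignments = rep(NA_integer_, nrow(calls)),
                          H = NA_real_, heterogeneous = NA,
                          assessable = FALSE),
                     class = "wex_clusters"))
  }
  ord <- order(ccf)
  fit <- with_seed(seed, suppressWarnings(
    Mclust(ccf[ord], G = seq_len(max_k),
           modelNames = c("E", "V"), verbose = FALSE)))
  cls <- integer(length(ccf))
  cls[ord] <- fit$classification
  prop <- as.numeric(table(factor(cls, levels = seq_len(fit$G)))) / length(cls)
  means <- fit$parameters$mean
  keep <- prop >= min_cluster_prop
  means <- means[keep]
  prop <- prop[keep] / sum(prop[keep])
  # re-map assignments of dropped clusters to the nearest kept mean
  remap <- vapply(seq_along(keep), function(j) {
    if (keep[j]) match(j, which(keep)) else
      which.min(abs(fit$parameters$mean[keep] - fit$parameters$mean[j]))
  }, integer(1))
  cls <- remap[cls]
  H <- shannon_index(prop)
  assignments <- rep(NA_integer_, nrow(calls))
  assignments[use] <- cls
  structure(list(sample_id = unique(calls$sample_id) %||% NA,
                 k = length(prop), means = unname(means),
                 proportions = unname(prop), assignments = assignments,
                 H = H$H, heterogeneous = H$heterogeneous, assessable = TRUE),
            class = "wex_clusters")
}

#' Shannon index of clonal cluster proportions
#'
#' `H = -sum(p_i * ln p_i)` (natural log); a sample is heterogeneous when
#' `H > 1`.
#'
#' @param proportions numeric vector summing to 1.
#' @return list with `H` and `heterogeneous`.
#' @export
shannon_index <- function(proportions) {
  assert_that(abs(sum(proportions) - 1) < 1e-6,
              "cluster proportions must sum to 1")
  p <- proportions[proportions > 0]
  H <- -sum(p * log(p))
  list(H = H, heterogeneous = H > 1)
}

#' Per-sample clonal-mutation fractions
#'
#' @param calls cohort clonality-call data.frame.
#' @param samples `wex_samples` data.frame for group labels.
#' @return data.frame with `sample_id`, `group`, `n_mutations`,
#'   `frac_clonal`, `frac_subclonal`.
#' @export
clonal_fraction_summary <- function(calls, samples) {
  out <- lapply(unique(calls$sample_id), function(sid) {
    cs <- calls[calls$sample_id == sid, ]
    data.frame(sample_id = sid,
               group = samples$group[samples$sample_id == sid],
               n_mutations = nrow(cs),
               frac_clonal = mean(cs$label == "Clonal"),
               frac_subclonal = mean(cs$label == "Subclonal"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
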