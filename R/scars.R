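# Genomic-scar HRD scoring from allele-specific copy-number segments:
# LOH (Abkevich-type), telomeric allelic imbalance (TAI), and large-scale
# state transitions (LST), summed into the HRD score with the >= 42
# high-HRD cutoff.
#
# Allelic imbalance means major != minor copy number (major = cn_total -
# cn_minor). Telomere touch uses a 1 kb tolerance: exome-derived segments
# rarely reach the literal chromosome end.

seg_len <- function(seg) seg$end - seg$start + 1

TELOMERE_TOL <- 1000

#' Smooth and arm-split one sample's segments for scar scoring
#'
#' Segments are split at the centromere (the centromeric interval itself is
#' removed), segments shorter than `min_keep_mb` are dropped, and flanking
#' segments with identical `(cn_total, cn_minor)` are merged, iterating
#' until stable.
#'
#' @param segments segment data.frame of one sample.
#' @param genome `wex_genome` data.frame.
#' @param min_keep_mb smoothing threshold in Mb; segments shorter than this
#'   are removed before merging.
#' @return data.frame of arm-local segments with an extra `arm` column.
#' @export
preprocess_segments <- function(segments, genome, min_keep_mb = 3) {
  if (nrow(segments) == 0) {
    return(cbind(segments, arm = character(0)))
  }
  gm <- genome_lookup(genome, segments$chrom)
  assert_that(all(segments$end <= gm$length),
              "segment end exceeds chromosome length")
  pieces <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, , drop = FALSE]
    g <- gm[i, ]
    out <- list()
    if (s$start < g$centromere_start) {
      p <- s; p$end <- min(p$end, g$centromere_start - 1); p$arm <- "p"
      out <- c(out, list(p))
    }
    if (s$end > g$centromere_end) {
      q <- s; q$start <- max(q$start, g$centromere_end + 1); q$arm <- "q"
      out <- c(out, list(q))
    }
    out
  })
  segs <- do.call(rbind, unlist(pieces, recursive = FALSE))
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  min_keep <- min_keep_mb * 1e6
  repeat {
    segs <- segs[seg_len(segs) >= min_keep, , drop = FALSE]
    if (nrow(segs) < 2) break
    merged <- FALSE
    keep <- rep(TRUE, nrow(segs))
    for (i in seq_len(nrow(segs) - 1)) {
      if (!keep[i]) next
      j <- i + 1
      while (j <= nrow(segs) && !keep[j]) j <- j + 1
      if (j > nrow(segs)) break
      same <- segs$chrom[i] == segs$chrom[j] && segs$arm[i] == segs$arm[j] &&
        segs$cn_total[i] == segs$cn_total[j] &&
        segs$cn_minor[i] == segs$cn_minor[j]
      if (same) {
        segs$end[i] <- segs$end[j]
        keep[j] <- FALSE
        merged <- TRUE
      }
    }
    segs <- segs[keep, , drop = FALSE]
    if (!merged) break
  }
  rownames(segs) <- NULL
  segs
}

is_imbalanced <- function(seg) seg$cn_minor != (seg$cn_total - seg$cn_minor)

# Whole-chromosome LOH: every retained segment of the chromosome has minor
# copy number 0 and the LOH stretch runs telomere to telomere (within
# tolerance, ignoring the centromeric gap).
chrom_whole_loh <- function(segs_chrom, chrom_len) {
  if (nrow(segs_chrom) == 0) return(FALSE)
  all(segs_chrom$cn_minor == 0) &&
    min(segs_chrom$start) <= 1 + TELOMERE_TOL &&
    max(segs_chrom$end) >= chrom_len - TELOMERE_TOL
}

#' Count HRD-LOH events
#'
#' Segments with minor copy number 0 and total copy number >= 1, longer than
#' `min_mb`, excluding chromosomes in whole-chromosome LOH.
#'
#' @param segments preprocessed (arm-split, smoothed) segments of one sample.
#' @param genome `wex_genome` data.frame.
#' @param min_mb minimum length in Mb (strict `>`).
#' @return integer count.
#' @export
count_hrd_loh <- function(segments, genome, min_mb = 15) {
  if (nrow(segments) == 0) return(0L)
  n <- 0L
  for (chrom in unique(segments$chrom)) {
    sc <- segments[segments$chrom == chrom, , drop = FALSE]
    len <- genome_lookup(genome, chrom)$length
    if (chrom_whole_loh(sc, len)) next
    loh <- sc$cn_minor == 0 & sc$cn_total >= 1 & seg_len(sc) > min_mb * 1e6
    n <- n + sum(loh)
  }
  as.integer(n)
}

#' Count telomeric allelic imbalance (TAI) events
#'
#' Allelically imbalanced segments that reach a telomere (outer boundary
#' within 1 kb of position 1 or the chromosome end), do not cross the
#' centromere (guaranteed by arm splitting), and are at least `min_mb` long.
#'
#' @param segments preprocessed segments of one sample.
#' @param genome `wex_genome` data.frame.
#' @param min_mb minimum segment length in Mb (`>=`).
#' @return integer count.
#' @export
count_tai <- function(segments, genome, min_mb = 11) {
  if (nrow(segments) == 0) return(0L)
  gm <- genome_lookup(genome, segments$chrom)
  touches_tel <- (segments$arm == "p" & segments$start <= 1 + TELOMERE_TOL) |
    (segments$arm == "q" & segments$end >= gm$length - TELOMERE_TOL)
  as.integer(sum(touches_tel & is_imbalanced(segments) &
                   seg_len(segments) >= min_mb * 1e6))
}

#' Count large-scale state transitions (LST)
#'
#' Per chromosome arm, breakpoints between adjacent segments with different
#' `(cn_total, cn_minor)`, both at least `min_mb` long, separated by a gap
#' smaller than `max_gap_mb`.
#'
#' @param segments preprocessed (3 Mb-smoothed) segments of one sample.
#' @param genome `wex_genome` data.frame (unused beyond interface symmetry;
#'   arm assignment happens in preprocessing).
#' @param min_mb minimum flanking-segment length in Mb (`>=`).
#' @param max_gap_mb maximum inter-segment gap in Mb (strict `<`).
#' @return integer count summed over arms.
#' @export
count_lst <- function(segments, genome, min_mb = 10, max_gap_mb = 3) {
  if (nrow(segments) < 2) return(0L)
  n <- 0L
  for (key in unique(paste(segments$chrom, segments$arm))) {
    sa <- segments[paste(segments$chrom, segments$arm) == key, , drop = FALSE]
    if (nrow(sa) < 2) next
    sa <- sa[order(sa$start), , drop = FALSE]
    for (i in seq_len(nrow(sa) - 1)) {
      a <- sa[i, ]; b <- sa[i + 1, ]
      different <- a$cn_total != b$cn_total || a$cn_minor != b$cn_minor
      big <- seg_len(a) >= min_mb * 1e6 && seg_len(b) >= min_mb * 1e6
      gap <- b$start - a$end - 1
      if (different && big && gap < max_gap_mb * 1e6) n <- n + 1L
    }
  }
  n
}

#' Combine scar counts into the HRD score
#'
#' @param n_loh,n_tai,n_lst nonnegative event counts.
#' @param sample_id optional sample identifier.
#' @param high_cut HRD-high threshold (inclusive `>=`).
#' @return list of class `wex_scars` with `n_loh`, `n_tai`, `n_lst`,
#'   `hrd_score`, `hrd_high`.
#' @export
hrd_score <- function(n_loh, n_tai, n_lst, sample_id = NA_character_,
                      high_cut = 42) {
  assert_that(n_loh >= 0 && n_tai >= 0 && n_lst >= 0,
              "scar counts must be nonnegative")
  score <- n_loh + n_tai + n_lst
  structure(list(sample_id = sample_id, n_loh = as.integer(n_loh),
                 n_tai = as.integer(n_tai), n_lst = as.integer(n_lst),
                 hrd_score = as.integer(score), hrd_high = score >= high_cut),
            class = "wex_scars")
}

#' Score one sample's segments
#' @param segments raw (validated) segments of one sample.
#' @param genome `wex_genome` data.frame.
#' @param sample_id sample identifier.
#' @param loh_min_mb,tai_min_mb,lst_min_mb,smooth_mb,high_cut scar-rule
#'   thresholds (defaults 15 / 11 / 10 / 3 Mb and 42).
#' @return `wex_scars` list.
#' @export
scar_scores <- function(segments, genome, sample_id = NA_character_,
                        loh_min_mb = 15, tai_min_mb = 11, lst_min_mb = 10,
                        smooth_mb = 3, high_cut = 42) {
  pp <- preprocess_segments(segments, genome, min_keep_mb = smooth_mb)
  hrd_score(count_hrd_loh(pp, genome, min_mb = loh_min_mb),
            count_tai(pp, genome, min_mb = tai_min_mb),
            count_lst(pp, genome, min_mb = lst_min_mb),
            sample_id = sample_id, high_cut = high_cut)
}

#' Score every sample in a cohort
#' @param dataset `wex_cohort` object.
#' @param genome `wex_genome` data.frame.
#' @param ... thresholds passed to [scar_scores()].
#' @return data.frame with one row per sample.
#' @export
cohort_scar_scores <- function(dataset, genome = load_hg19_genome(), ...) {
  out <- lapply(dataset$samples$sample_id, function(sid) {
    s <- scar_scores(
      dataset$segments[dataset$segments$sample_id == sid, , drop = FALSE],
      genome, sample_id = sid, ...)
    data.frame(sample_id = sid, n_loh = s$n_loh, n_tai = s$n_tai,
               n_lst = s$n_lst, hrd_score = s$hrd_score,
               hrd_high = s$hrd_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
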