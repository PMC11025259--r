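# Synthetic cohort generator with known ground truth.
#
# Every statistical structure the pipeline assumes is emulated: signature-
# driven trinucleotide spectra, clonal architectures with binomial read
# sampling given purity/copy-number/depth, allele-specific segment profiles
# carrying exactly the requested numbers of qualifying LOH/TAI/LST events,
# and group/subtype effects. Scar events are constructed directly from the
# written scoring definitions (segment sizes, telomere/centromere geometry,
# copy-number states), not by calling the scorer, so scorer tests against
# the generator are a genuine dual route.

#' Simulation configuration
#'
#' Defaults emulate a two-group tumor-exome cohort: 24 samples per group;
#' negative-binomial per-sample mutation counts with a long right tail;
#' subtype mixes with more HER2+ and TN disease in the IBC group; an
#' age-related-signature excess in the non-IBC group; one- versus
#' three-cluster clonal architectures (the heterogeneous archetype is rarer
#' in IBC); subtype-dependent genomic-scar burdens with the TN excess
#' concentrated in IBC; and sequencing depth around 180x.
#'
#' @param n_per_group named integer vector, samples per group.
#' @param subtype_probs list of per-group subtype probability vectors.
#' @param mut_mu,mut_size negative-binomial mean and dispersion of the
#'   per-sample mutation count (floored at `mut_min`).
#' @param mut_min minimum mutations per sample.
#' @param indel_prob per-group probability that a mutation is an indel.
#' @param depth_meanlog,depth_sdlog log-normal read-depth parameters.
#' @param purity_range uniform purity range.
#' @param panel_size_mb exome territory in Mb.
#' @param signature_weights list of per-group named weight vectors over the
#'   reference catalog.
#' @param novel_profile optional 96-vector mixed into every IBC sample's
#'   profile with weight `novel_weight` (for the novel-signature scenario).
#' @param novel_weight mixing weight of `novel_profile`.
#' @param het_prob per-group probability of the heterogeneous (3-cluster)
#'   clonal archetype.
#' @param clusters_homogeneous,clusters_heterogeneous data.frames with
#'   columns `ccf`, `prop` describing the two clonal archetypes.
#' @param scar_low,scar_high named vectors (`loh`, `tai`, `lst`) of Poisson
#'   means for the two scar archetypes.
#' @param scar_high_prob function(group, subtype) -> probability of the
#'   high-scar archetype.
#' @param erbb2_amp_prob,pik3ca_hotspot_prob,pten_del_prob,brca_del_prob
#'   per-sample gene-alteration probabilities (ERBB2 amplification applies
#'   to HER2+ samples only).
#' @return list of class `wex_sim_config`.
#' @export
sim_config <- function(
    n_per_group = c(IBC = 24, nonIBC = 24),
    subtype_probs = list(
      IBC = c(HRpos_HER2neg = 0.37, HER2pos = 0.41, TN = 0.22),
      nonIBC = c(HRpos_HER2neg = 0.60, HER2pos = 0.20, TN = 0.20)),
    mut_mu = 80, mut_size = 1.3, mut_min = 10,
    indel_prob = c(IBC = 0.04, nonIBC = 0.10),
    depth_meanlog = log(180), depth_sdlog = 0.25,
    purity_range = c(0.6, 0.95),
    panel_size_mb = 38,
    signature_weights = list(
      IBC = c(S1 = 0.30, S2 = 0.20, S13 = 0.20, S3 = 0.20, S6 = 0.10),
      nonIBC = c(S1 = 0.45, S2 = 0.15, S13 = 0.10, S3 = 0.20, S6 = 0.10)),
    novel_profile = NULL, novel_weight = 0.15,
    het_prob = c(IBC = 0.21, nonIBC = 0.33),
    clusters_homogeneous = data.frame(ccf = 1.0, prop = 1.0),
    clusters_heterogeneous = data.frame(ccf = c(1.0, 0.6, 0.25),
                                        prop = c(1, 1, 1) / 3),
    scar_low = c(loh = 4, tai = 3, lst = 5),
    scar_high = c(loh = 14, tai = 11, lst = 19),
    scar_high_prob = function(group, subtype) {
      if (subtype == "TN") { if (group == "IBC") 0.6 else 0.35 }
      else 0.12
    },
    erbb2_amp_prob = 0.9, pik3ca_hotspot_prob = 0.2,
    pten_del_prob = 0.06, brca_del_prob = 0.08) {
  cfg <- as.list(environment())
  for (arc in list(cfg$clusters_homogeneous, cfg$clusters_heterogeneous))
    assert_that(abs(sum(arc$prop) - 1) < 1e-8,
                "cluster proportions must sum to 1")
  assert_that(all(cfg$clusters_heterogeneous$ccf <= 1),
              "cluster CCF above 1 is infeasible")
  class(cfg) <- "wex_sim_config"
  cfg
}

PIK3CA_HOTSPOTS <- c("H1047R", "E545K", "E542K")

# ---- segment construction ---------------------------------------------------

MB <- 1e6

seg_row <- function(sample_id, chrom, start, end, total, minor) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cn_total = total, cn_minor = minor, stringsAsFactors = FALSE)
}

# Fill an arm with an LOH chain: [3 filler][9 buffer][20 LOH][9 buffer]...
# Buffers are balanced (4,2) so they add no TAI; all breakpoints have a
# sub-10 Mb side so they add no LST.
arm_loh_chain <- function(sid, chrom, a_start, a_end, n_events) {
  segs <- list()
  pos <- a_start
  segs[[1]] <- seg_row(sid, chrom, pos, pos + 3 * MB - 1, 2, 1); pos <- pos + 3 * MB
  for (i in seq_len(n_events)) {
    segs[[length(segs) + 1]] <- seg_row(sid, chrom, pos, pos + 9 * MB - 1, 4, 2)
    pos <- pos + 9 * MB
    segs[[length(segs) + 1]] <- seg_row(sid, chrom, pos, pos + 20 * MB - 1, 1, 0)
    pos <- pos + 20 * MB
  }
  segs[[length(segs) + 1]] <- seg_row(sid, chrom, pos, pos + 9 * MB - 1, 4, 2)
  pos <- pos + 9 * MB
  segs[[length(segs) + 1]] <- seg_row(sid, chrom, pos, a_end, 2, 1)
  do.call(rbind, segs)
}

# Telomeric allelic imbalance: [15 Mb (3,1) at the telomere][9 buffer][rest].
arm_tai_event <- function(sid, chrom, a_start, a_end, arm) {
  if (arm == "p") {
    rbind(seg_row(sid, chrom, a_start, a_start + 15 * MB - 1, 3, 1),
          seg_row(sid, chrom, a_start + 15 * MB, a_start + 24 * MB - 1, 4, 2),
          seg_row(sid, chrom, a_start + 24 * MB, a_end, 2, 1))
  } else {
    rbind(seg_row(sid, chrom, a_start, a_end - 24 * MB, 2, 1),
          seg_row(sid, chrom, a_end - 24 * MB + 1, a_end - 15 * MB, 4, 2),
          seg_row(sid, chrom, a_end - 15 * MB + 1, a_end, 3, 1))
  }
}

# LST breakpoints: a balanced 12 Mb (4,2) block flanked by >= 10 Mb diploid
# filler gives 2 transitions; the same block placed at the arm start gives 1.
arm_lst_event <- function(sid, chrom, a_start, a_end, n_break) {
  if (n_break == 2) {
    mid <- a_start + floor((a_end - a_start) / 2)
    rbind(seg_row(sid, chrom, a_start, mid - 6 * MB - 1, 2, 1),
          seg_row(sid, chrom, mid - 6 * MB, mid + 6 * MB - 1, 4, 2),
          seg_row(sid, chrom, mid + 6 * MB, a_end, 2, 1))
  } else {
    rbind(seg_row(sid, chrom, a_start, a_start + 12 * MB - 1, 4, 2),
          seg_row(sid, chrom, a_start + 12 * MB, a_end, 2, 1))
  }
}

arm_diploid <- function(sid, chrom, a_start, a_end)
  seg_row(sid, chrom, a_start, a_end, 2, 1)

# Chromosome carrying focal gene events: diploid filler around each block.
chrom_with_gene_events <- function(sid, chrom, chrom_len, events) {
  events <- events[order(events$start), , drop = FALSE]
  segs <- list()
  pos <- 1
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$start > pos)
      segs[[length(segs) + 1]] <- seg_row(sid, chrom, pos, e$start - 1, 2, 1)
    segs[[length(segs) + 1]] <- seg_row(sid, chrom, e$start, e$end,
                                        e$cn_total, e$cn_minor)
    pos <- e$end + 1
  }
  if (pos <= chrom_len)
    segs[[length(segs) + 1]] <- seg_row(sid, chrom, pos, chrom_len, 2, 1)
  do.call(rbind, segs)
}

GENE_EVENT_DEFS <- list(
  erbb2_amp = list(chrom = "chr17", start = 34 * MB, end = 42 * MB - 1,
                   cn_total = 8, cn_minor = 1),
  brca1_del = list(chrom = "chr17", start = 40.5 * MB, end = 48 * MB,
                   cn_total = 0, cn_minor = 0),
  pten_del = list(chrom = "chr10", start = 85 * MB, end = 93 * MB,
                  cn_total = 0, cn_minor = 0),
  brca2_del = list(chrom = "chr13", start = 30 * MB, end = 38 * MB,
                   cn_total = 0, cn_minor = 0))

# Chromosomes that may carry focal gene events; scar events avoid them so
# that scar counts and gene calls stay independently controlled.
RESERVED_CHROMS <- c("chr17", "chr10", "chr13", "chr3")

#' Construct a segment profile carrying exact scar-event counts
#'
#' Builds an allele-specific copy-number profile containing exactly
#' `targets["loh"]` qualifying LOH events (> 15 Mb, sub-chromosome),
#' `targets["tai"]` telomeric allelic imbalances, and `targets["lst"]`
#' large-scale transitions, plus diploid heterozygous filler and optional
#' focal gene-level events on reserved chromosomes. Events are placed from
#' the scoring definitions' geometry; arms are allocated deterministically
#' by length.
#'
#' @param sample_id sample identifier.
#' @param targets named vector/list with `loh`, `tai`, `lst` counts.
#' @param genome `wex_genome` data.frame.
#' @param gene_events character subset of
#'   `c("erbb2_amp", "brca1_del", "pten_del", "brca2_del")`.
#' @return `wex_segments`-schema data.frame covering every autosome and X.
#' @export
simulate_segments <- function(sample_id, targets, genome,
                              gene_events = character(0)) {
  targets <- lapply(targets, as.integer)
  arms <- chromosome_arms(genome)
  arms <- arms[arms$chrom != "chrY", ]
  arms$len <- arms$end - arms$start + 1
  free <- arms[!arms$chrom %in% RESERVED_CHROMS, ]
  free <- free[order(-free$len), ]
  plan <- list()
  used <- rep(FALSE, nrow(free))

  # TAI first, on the shortest adequate arms (one per arm)
  tai_left <- targets$tai
  if (tai_left > 0) {
    cand <- rev(which(!used & free$len >= 27 * MB))
    assert_that(length(cand) >= tai_left,
                "more TAI events requested than placeable arms")
    for (i in cand[seq_len(tai_left)]) {
      plan[[length(plan) + 1]] <- list(kind = "tai", row = i)
      used[i] <- TRUE
    }
  }
  # LOH chains on the longest remaining arms
  loh_left <- targets$loh
  while (loh_left > 0) {
    cand <- which(!used & free$len >= 44 * MB)
    assert_that(length(cand) > 0,
                "more LOH events requested than placeable arms")
    i <- cand[1]
    cap <- floor((free$len[i] - 15 * MB) / (29 * MB))
    n <- min(cap, loh_left)
    plan[[length(plan) + 1]] <- list(kind = "loh", row = i, n = n)
    used[i] <- TRUE
    loh_left <- loh_left - n
  }
  # LST: 2 breakpoints per >= 32 Mb arm, 1 on a >= 22 Mb arm for odd counts
  lst_left <- targets$lst
  while (lst_left > 0) {
    if (lst_left >= 2) {
      cand <- which(!used & free$len >= 32 * MB)
      assert_that(length(cand) > 0,
                  "more LST events requested than placeable arms")
      i <- cand[1]
      plan[[length(plan) + 1]] <- list(kind = "lst", row = i, n = 2)
      used[i] <- TRUE
      lst_left <- lst_left - 2
    } else {
      cand <- which(!used & free$len >= 22 * MB)
      assert_that(length(cand) > 0,
                  "more LST events requested than placeable arms")
      i <- cand[1]
      plan[[length(plan) + 1]] <- list(kind = "lst", row = i, n = 1)
      used[i] <- TRUE
      lst_left <- lst_left - 1
    }
  }

  segs <- list()
  for (p in plan) {
    a <- free[p$row, ]
    segs[[length(segs) + 1]] <- switch(
      p$kind,
      tai = arm_tai_event(sample_id, a$chrom, a$start, a$end, a$arm),
      loh = arm_loh_chain(sample_id, a$chrom, a$start, a$end, p$n),
      lst = arm_lst_event(sample_id, a$chrom, a$start, a$end, p$n))
  }
  # untouched free arms -> diploid filler
  for (i in which(!used))
    segs[[length(segs) + 1]] <- arm_diploid(sample_id, free$chrom[i],
                                            free$start[i], free$end[i])
  # reserved chromosomes: diploid, with requested focal gene events
  for (chrom in RESERVED_CHROMS) {
    len <- genome_lookup(genome, chrom)$length
    ev <- Filter(function(nm) GENE_EVENT_DEFS[[nm]]$chrom == chrom, gene_events)
    if (length(ev) == 0) {
      segs[[length(segs) + 1]] <- seg_row(sample_id, chrom, 1, len, 2, 1)
    } else {
      evdf <- do.call(rbind, lapply(ev, function(nm)
        as.data.frame(GENE_EVENT_DEFS[[nm]], stringsAsFactors = FALSE)))
      segs[[length(segs) + 1]] <- chrom_with_gene_events(sample_id, chrom,
                                                         len, evdf)
    }
  }
  out <- do.call(rbind, segs)
  as_segments(out)
}

# ---- mutation construction --------------------------------------------------

channel_to_mutation <- function(channel) {
  # "A[C>T]G" -> ref/alt on the pyrimidine strand plus its 3-mer context
  f5 <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  f3 <- substr(channel, 7, 7)
  list(ref = ref, alt = alt, context3 = paste0(f5, ref, f3))
}

draw_positions <- function(segments, n) {
  # sample positions on diploid-heterozygous segments, weighted by length
  dip <- segments[segments$cn_total == 2 & segments$cn_minor == 1, ,
                  drop = FALSE]
  w <- dip$end - dip$start + 1
  idx <- sample.int(nrow(dip), n, replace = TRUE, prob = w)
  data.frame(chrom = dip$chrom[idx],
             pos = dip$start[idx] +
               floor(stats::runif(n) * (dip$end[idx] - dip$start[idx] - 2)) + 1)
}

VARIANT_CLASS_PROBS_SNV <- c(missense = 0.675, nonsense = 0.035,
                             splice = 0.02, silent = 0.27)

#' Simulate one sample's mutation records
#'
#' Each mutation is assigned a clonal cluster, its expected VAF follows the
#' purity/copy-number model (`VAF = CCF * p * m / (p * n_t + 2(1 - p))`,
#' with m = 1 and n_t = 2 on the diploid segments used for placement), read
#' counts are binomial at a log-normally drawn depth, and the substitution
#' plus trinucleotide context are sampled from the sample's mixed signature
#' profile.
#'
#' @param sample_id sample identifier.
#' @param n_mutations number of mutations.
#' @param signature_weights named weights over `reference` columns.
#' @param clusters data.frame with columns `ccf`, `prop`.
#' @param purity tumor purity.
#' @param segments the sample's segment profile (for placement).
#' @param reference signature catalog (96 x k).
#' @param indel_prob probability a mutation is an indel.
#' @param depth_meanlog,depth_sdlog depth distribution parameters.
#' @param extra_profile,extra_weight optional additional 96-profile mixed
#'   into the sample's signature profile.
#' @return list with `mutations` (mutation-table data.frame with `context3`)
#'   and `truth` (per-mutation `cluster`, `true_ccf`, `true_label`).
#' @export
simulate_sample_mutations <- function(sample_id, n_mutations,
                                      signature_weights, clusters, purity,
                                      segments,
                                      reference = reference_signatures(),
                                      indel_prob = 0.05,
                                      depth_meanlog = log(180),
                                      depth_sdlog = 0.25,
                                      extra_profile = NULL,
                                      extra_weight = 0) {
  assert_that(all(names(signature_weights) %in% colnames(reference)),
              "signature_weights name signatures absent from the reference")
  profile <- as.numeric(reference[, names(signature_weights), drop = FALSE] %*%
                          (signature_weights / sum(signature_weights)))
  if (!is.null(extra_profile)) {
    profile <- (1 - extra_weight) * profile + extra_weight * extra_profile
  }
  if (n_mutations == 0) {
    return(list(mutations = data.frame(), truth = data.frame()))
  }
  cl <- sample.int(nrow(clusters), n_mutations, replace = TRUE,
                   prob = clusters$prop)
  ccf <- clusters$ccf[cl]
  exp_vaf <- ccf * purity * 1 / ccf_denominator(purity, 2)
  assert_that(all(exp_vaf <= 1), "infeasible configuration: expected VAF > 1")
  depth <- pmax(30L, as.integer(round(stats::rlnorm(n_mutations,
                                                    depth_meanlog,
                                                    depth_sdlog))))
  alt <- stats::rbinom(n_mutations, depth, exp_vaf)
  alt[alt == 0 & exp_vaf > 0] <- 1L
  pos <- draw_positions(segments, n_mutations)
  is_indel <- stats::runif(n_mutations) < indel_prob
  channels <- sample(sbs96_channels(), n_mutations, replace = TRUE,
                     prob = profile)
  info <- lapply(channels, channel_to_mutation)
  ref <- vapply(info, `[[`, character(1), "ref")
  alt_allele <- vapply(info, `[[`, character(1), "alt")
  ctx <- vapply(info, `[[`, character(1), "context3")
  vclass <- character(n_mutations)
  snv_classes <- sample(names(VARIANT_CLASS_PROBS_SNV), n_mutations,
                        replace = TRUE, prob = VARIANT_CLASS_PROBS_SNV)
  vclass[!is_indel] <- snv_classes[!is_indel]
  vclass[is_indel] <- sample(c("frameshift_indel", "inframe_indel"),
                             sum(is_indel), replace = TRUE,
                             prob = c(0.8, 0.2))
  # indels: extend the ref allele; their context column is not used
  ref[is_indel] <- paste0(ref[is_indel], "A")
  ctx[is_indel] <- NA_character_
  gene_pool <- c("TP53", "PIK3CA", "KMT2C", "GATA3", "MAP2K4", "ARID1A")
  gene <- ifelse(stats::runif(n_mutations) < 0.03,
                 sample(gene_pool, n_mutations, replace = TRUE),
                 sprintf("GENE%04d", sample.int(4000, n_mutations,
                                                replace = TRUE)))
  mut <- data.frame(
    sample_id = sample_id, chrom = pos$chrom, pos = pos$pos,
    ref = ref, alt = alt_allele, gene = gene, variant_class = vclass,
    variant_type = ifelse(is_indel, "indel", "SNV"),
    alt_count = alt, ref_count = depth - alt,
    context3 = ctx, protein_change = NA_character_,
    stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_id, cluster = cl, true_ccf = ccf,
                      true_label = ifelse(ccf >= 0.95, "Clonal", "Subclonal"),
                      stringsAsFactors = FALSE)
  list(mutations = mut, truth = truth)
}

# ---- whole-cohort simulation ------------------------------------------------

#' Simulate a two-group cohort with ground truth
#'
#' Deterministic given `seed`. Emits a full `wex_cohort` (mutation table
#' with contexts, allele-specific segments, sample sheet) plus per-sample
#' ground truth: signature weights, clonal architecture, per-mutation
#' labels, scar counts, heterogeneity flag and injected gene events.
#'
#' @param config `wex_sim_config` from [sim_config()].
#' @param seed integer seed (mandatory).
#' @param genome `wex_genome` data.frame.
#' @return list with `dataset` (`wex_cohort`) and `truth` (list with
#'   `samples` data.frame and `mutations` data.frame).
#' @export
simulate_cohort <- function(config = sim_config(), seed,
                            genome = load_hg19_genome()) {
  assert_that(!missing(seed), "seed is mandatory")
  reference <- reference_signatures()
  with_seed(seed, {
    samples <- list(); muts <- list(); segs <- list()
    truth_s <- list(); truth_m <- list()
    for (group in names(config$n_per_group)) {
      n <- config$n_per_group[[group]]
      if (n == 0) next
      probs <- config$subtype_probs[[group]]
      for (i in seq_len(n)) {
        sid <- sprintf("%s%03d", group, i)
        subtype <- sample(names(probs), 1, prob = probs)
        purity <- stats::runif(1, config$purity_range[1],
                               config$purity_range[2])
        age <- round(if (group == "IBC") stats::rnorm(1, 48, 9)
                     else stats::rnorm(1, 58, 11))
        age <- min(max(age, 25), 90)
        # scar archetype
        p_high <- config$scar_high_prob(group, subtype)
        arch <- if (stats::runif(1) < p_high) config$scar_high else config$scar_low
        # caps keep extreme Poisson draws within the genome's arm capacity
        targets <- list(loh = min(stats::rpois(1, arch[["loh"]]), 18L),
                        tai = min(stats::rpois(1, arch[["tai"]]), 14L),
                        lst = min(stats::rpois(1, arch[["lst"]]), 24L))
        # focal gene events
        ev <- character(0)
        if (subtype == "HER2pos" && stats::runif(1) < config$erbb2_amp_prob)
          ev <- c(ev, "erbb2_amp")
        if (subtype == "TN" && stats::runif(1) < config$brca_del_prob)
          ev <- c(ev, sample(c("brca1_del", "brca2_del"), 1))
        if (stats::runif(1) < config$pten_del_prob) ev <- c(ev, "pten_del")
        seg <- simulate_segments(sid, targets, genome, gene_events = ev)
        # clonal architecture
        het <- stats::runif(1) < config$het_prob[[group]]
        clusters <- if (het) config$clusters_heterogeneous
                    else config$clusters_homogeneous
        n_mut <- max(config$mut_min,
                     stats::rnbinom(1, size = config$mut_size,
                                    mu = config$mut_mu))
        sm <- simulate_sample_mutations(
          sid, n_mut, config$signature_weights[[group]], clusters, purity,
          seg, reference = reference,
          indel_prob = config$indel_prob[[group]],
          depth_meanlog = config$depth_meanlog,
          depth_sdlog = config$depth_sdlog,
          extra_profile = if (group == "IBC") config$novel_profile else NULL,
          extra_weight = config$novel_weight)
        mut <- sm$mutations
        # PIK3CA hotspot carrier: upgrade one clonal missense mutation
        hotspot <- stats::runif(1) < config$pik3ca_hotspot_prob
        if (hotspot && nrow(mut) > 0) {
          j <- which(sm$truth$true_label == "Clonal" &
                       mut$variant_type == "SNV")[1]
          if (!is.na(j)) {
            mut$gene[j] <- "PIK3CA"
            mut$variant_class[j] <- "missense"
            mut$protein_change[j] <- sample(PIK3CA_HOTSPOTS, 1)
          }
        }
        true_H <- shannon_index(clusters$prop)
        samples[[sid]] <- data.frame(
          sample_id = sid, group = group, subtype = subtype, age = age,
          purity = purity, ploidy = 2.0,
          panel_size_mb = config$panel_size_mb, stringsAsFactors = FALSE)
        muts[[sid]] <- mut
        segs[[sid]] <- seg
        truth_s[[sid]] <- data.frame(
          sample_id = sid, group = group, subtype = subtype,
          n_loh = targets$loh, n_tai = targets$tai, n_lst = targets$lst,
          hrd_score = targets$loh + targets$tai + targets$lst,
          heterogeneous = true_H$heterogeneous, true_H = true_H$H,
          n_clusters = nrow(clusters), n_mutations = n_mut,
          erbb2_amp = "erbb2_amp" %in% ev,
          pten_del = "pten_del" %in% ev,
          brca_del = any(c("brca1_del", "brca2_del") %in% ev),
          pik3ca_hotspot = hotspot, stringsAsFactors = FALSE)
        truth_m[[sid]] <- sm$truth
        truth_s[[sid]]$signature_weights <- I(list(
          config$signature_weights[[group]]))
      }
    }
    empty_mut <- data.frame(sample_id = character(0), chrom = character(0),
                            pos = integer(0), ref = character(0),
                            alt = character(0), gene = character(0),
                            variant_class = character(0),
                            variant_type = character(0),
                            alt_count = integer(0), ref_count = integer(0),
                            context3 = character(0),
                            protein_change = character(0),
                            stringsAsFactors = FALSE)
    empty_seg <- data.frame(sample_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            cn_total = numeric(0), cn_minor = numeric(0),
                            stringsAsFactors = FALSE)
    empty_samp <- data.frame(sample_id = character(0), group = character(0),
                             subtype = character(0), age = numeric(0),
                             purity = numeric(0), ploidy = numeric(0),
                             panel_size_mb = numeric(0),
                             stringsAsFactors = FALSE)
    dataset <- cohort_dataset(
      if (length(muts)) do.call(rbind, unname(muts)) else empty_mut,
      if (length(segs)) do.call(rbind, unname(segs)) else empty_seg,
      if (length(samples)) do.call(rbind, unname(samples)) else empty_samp)
    list(dataset = dataset,
         truth = list(
           samples = if (length(truth_s)) do.call(rbind, unname(truth_s))
                     else data.frame(),
           mutations = if (length(truth_m)) do.call(rbind, unname(truth_m))
                       else data.frame()))
  })
}
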