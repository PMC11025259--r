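# 96-context single-base-substitution spectra, pyrimidine-centric
# (COSMIC-style channel order).

SUBSTITUTIONS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 SBS channel names in canonical order
#'
#' Channels are ordered by substitution (C>A, C>G, C>T, T>A, T>C, T>G), then
#' 5' base (A, C, G, T), then 3' base (A, C, G, T); names look like
#' `"A[C>A]A"`. All spectra, reference catalogs, and NMF factors in this
#' package use this order.
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SUBSTITUTIONS6, function(sub) {
    ref <- substr(sub, 1, 1)
    unlist(lapply(BASES, function(b5)
      paste0(b5, "[", sub, "]", vapply(BASES, identity, character(1)))))
  }), use.names = FALSE)
}

# Map one SNV (ref, alt, 3-mer context) to its pyrimidine-strand channel.
# Purine-reference substitutions are reverse-complemented. Returns NA when
# the context is absent or its middle base disagrees with ref.
sbs96_channel_of <- function(ref, alt, context3) {
  if (is.na(context3) || nchar(context3) != 3) return(NA_character_)
  if (substr(context3, 2, 2) != ref) return(NA_character_)
  if (ref %in% c("G", "A")) {
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
    context3 <- revcomp(context3)
  }
  sub <- paste0(ref, ">", alt)
  if (!sub %in% SUBSTITUTIONS6) return(NA_character_)
  paste0(substr(context3, 1, 1), "[", sub, "]", substr(context3, 3, 3))
}

#' Build the 96-context spectrum of one sample
#'
#' Bins the sample's SNVs into the 96 pyrimidine-centric channels.
#' Purine-reference SNVs are reverse-complemented onto the pyrimidine strand.
#' SNVs without a usable context (missing, at a chromosome edge, or with a
#' middle base disagreeing with `ref`) are excluded and counted in
#' `n_excluded`, so `sum(counts) + n_excluded` always equals the number of
#' input SNVs.
#'
#' @param mutations mutation data.frame of one sample (indels are ignored).
#' @param reference optional reference source for [trinucleotide_context()]
#'   lookup of rows lacking `context3`.
#' @return list of class `wex_spectrum96` with `sample_id`, `counts` (named
#'   integer vector of length 96), `n_excluded`.
#' @export
build_spectrum96 <- function(mutations, reference = NULL) {
  snv <- mutations[mutations$variant_type == "SNV", , drop = FALSE]
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96), channels)
  n_excluded <- 0L
  ctx <- if (!is.null(snv$context3)) snv$context3 else rep(NA_character_, nrow(snv))
  if (!is.null(reference)) {
    need <- which(is.na(ctx))
    for (i in need)
      ctx[i] <- trinucleotide_context(snv$chrom[i], snv$pos[i], reference)
  }
  for (i in seq_len(nrow(snv))) {
    ch <- sbs96_channel_of(snv$ref[i], snv$alt[i], ctx[i])
    if (is.na(ch)) n_excluded <- n_excluded + 1L else counts[ch] <- counts[ch] + 1L
  }
  structure(list(sample_id = unique(snv$sample_id) %||% NA_character_,
                 counts = counts, n_excluded = n_excluded),
            class = "wex_spectrum96")
}

#' Stack per-sample spectra into a 96 x n matrix
#' @param dataset `wex_cohort` object.
#' @param reference optional context reference, see [build_spectrum96()].
#' @return numeric matrix, rows = 96 channels, columns = samples.
#' @export
spectra_matrix <- function(dataset, reference = NULL) {
  sids <- dataset$samples$sample_id
  m <- vapply(sids, function(sid) {
    build_spectrum96(
      dataset$mutations[dataset$mutations$sample_id == sid, , drop = FALSE],
      reference)$counts
  }, numeric(96))
  rownames(m) <- sbs96_channels()
  colnames(m) <- sids
  m
}

#' Collapse a 96-channel spectrum to the six substitution classes
#' @param counts numeric vector of length 96 in canonical channel order.
#' @return named numeric vector of length 6.
#' @export
collapse_spectrum6 <- function(counts) {
  assert_that(length(counts) == 96, "expected a 96-channel spectrum")
  stats::setNames(vapply(seq_len(6), function(i)
    sum(counts[((i - 1) * 16 + 1):(i * 16)]), numeric(1)), SUBSTITUTIONS6)
}
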