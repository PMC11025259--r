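#' Load a genome model table
#'
#' A genome model gives, per chromosome, the total length and the centromere
#' interval; chromosome arms are derived from these. The scar scores (TAI and
#' LST telomere/centromere rules) and segment preprocessing require it.
#'
#' @param path TSV with columns `chrom`, `length`, `centromere_start`,
#'   `centromere_end` (1-based bp). Lines starting with `#` are ignored.
#' @return A data.frame of class `wex_genome` with one row per chromosome.
#' @export
read_genome_model <- function(path) {
  gm <- read_wex_tsv(path)
  require_columns(gm, c("chrom", "length", "centromere_start", "centromere_end"),
                  "genome model table")
  gm$chrom <- as.character(gm$chrom)
  for (col in c("length", "centromere_start", "centromere_end"))
    gm[[col]] <- as.numeric(gm[[col]])
  ok <- gm$centromere_start > 0 & gm$centromere_start < gm$centromere_end &
    gm$centromere_end < gm$length
  assert_that(all(ok),
              sprintf("invalid centromere interval for: %s",
                      paste(gm$chrom[!ok], collapse = ", ")))
  assert_that(!anyDuplicated(gm$chrom), "duplicated chromosome in genome model")
  class(gm) <- c("wex_genome", "data.frame")
  gm
}

#' Bundled hg19 genome model
#'
#' Chromosome lengths and centromere intervals of the UCSC hg19 assembly
#' (autosomes plus X and Y), as shipped with the package.
#'
#' @return A `wex_genome` data.frame.
#' @export
load_hg19_genome <- function() {
  read_genome_model(wex_extdata("hg19_genome.tsv"))
}

#' Chromosome arm table derived from a genome model
#'
#' @param genome A `wex_genome` data.frame.
#' @return data.frame with columns `chrom`, `arm` ("p"/"q"), `start`, `end`.
#' @export
chromosome_arms <- function(genome) {
  p <- data.frame(chrom = genome$chrom, arm = "p", start = 1,
                  end = genome$centromere_start - 1)
  q <- data.frame(chrom = genome$chrom, arm = "q",
                  start = genome$centromere_end + 1, end = genome$length)
  arms <- rbind(p, q)
  arms[order(match(arms$chrom, genome$chrom), arms$arm), , drop = FALSE]
}

genome_lookup <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  assert_that(!anyNA(i),
              sprintf("chromosome(s) not in genome model: %s",
                      paste(unique(chrom[is.na(i)]), collapse = ", ")))
  genome[i, , drop = FALSE]
}
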