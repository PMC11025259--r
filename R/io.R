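# Readers and validation for the three cohort tables (MAF-like mutations,
# SEG-like allele-specific copy-number segments, sample sheet), plus the
# gene model and reference-genome context lookup.
#
# Coordinate convention, used everywhere in this package: 1-based, closed
# intervals, matching MAF and SEG files. Segment length = end - start + 1.

VARIANT_CLASSES <- c("missense", "nonsense", "silent", "splice",
                     "frameshift_indel", "inframe_indel", "other")
SUBTYPES <- c("HRpos_HER2neg", "HER2pos", "TN")
GROUPS <- c("IBC", "nonIBC")

# Extensible synonym table mapping common MAF Variant_Classification terms
# onto the controlled vocabulary; unmapped terms become "other" with a warning.
variant_class_synonyms <- function() {
  c(missense = "missense", Missense_Mutation = "missense",
    nonsense = "nonsense", Nonsense_Mutation = "nonsense",
    silent = "silent", Silent = "silent", Synonymous = "silent",
    splice = "splice", Splice_Site = "splice", Splice_Region = "splice",
    frameshift_indel = "frameshift_indel",
    Frame_Shift_Del = "frameshift_indel", Frame_Shift_Ins = "frameshift_indel",
    inframe_indel = "inframe_indel",
    In_Frame_Del = "inframe_indel", In_Frame_Ins = "inframe_indel",
    Nonstop_Mutation = "other", Translation_Start_Site = "other",
    other = "other")
}

normalize_variant_class <- function(x) {
  syn <- variant_class_synonyms()
  out <- unname(syn[x])
  unknown <- unique(x[is.na(out)])
  if (length(unknown)) {
    warning(sprintf("unmapped variant_class value(s) set to 'other': %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    out[is.na(out)] <- "other"
  }
  out
}

#' Read a somatic mutation table
#'
#' Parses a tab-separated MAF-like mutation table. `variant_type` is derived
#' from allele lengths when absent (SNV iff both alleles are single bases);
#' `variant_class` labels are mapped through a synonym table covering common
#' MAF terms. Row order is preserved.
#'
#' @param path TSV with header; `#` comment lines ignored.
#' @param columns Optional named character vector remapping the file's column
#'   names onto the expected schema, e.g.
#'   `c(sample_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol")`.
#' @return data.frame of class `wex_mutations` with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `variant_class`, `variant_type`,
#'   `alt_count`, `ref_count`, and optionally `context3`, `protein_change`.
#' @export
read_mutation_table <- function(path, columns = NULL) {
  df <- read_wex_tsv(path)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (columns[[std]] %in% names(df)) {
        names(df)[names(df) == columns[[std]]] <- std
      }
    }
  }
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                "variant_class", "alt_count", "ref_count")
  require_columns(df, required, "mutation table")
  as_mutations(df)
}

#' Validate and normalize a mutation data.frame
#'
#' @param df data.frame with the mutation-table schema (see
#'   [read_mutation_table()]).
#' @return validated `wex_mutations` data.frame.
#' @export
as_mutations <- function(df) {
  for (col in c("sample_id", "chrom", "ref", "alt", "gene"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("pos", "alt_count", "ref_count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != round(v))
    assert_that(length(bad) == 0,
                sprintf("non-integer value in column '%s' at row(s): %s",
                        col, paste(utils::head(bad, 5), collapse = ", ")),
                "wexscape_parse_error")
    df[[col]] <- as.integer(round(v))
  }
  assert_that(all(df$pos >= 1), "mutation pos must be >= 1")
  assert_that(all(df$alt_count >= 0 & df$ref_count >= 0),
              "read counts must be nonnegative")
  df$variant_class <- normalize_variant_class(as.character(df$variant_class))
  is_snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1
  if (is.null(df$variant_type)) {
    df$variant_type <- ifelse(is_snv, "SNV", "indel")
  } else {
    df$variant_type <- as.character(df$variant_type)
    assert_that(all((df$variant_type == "SNV") == is_snv),
                "variant_type inconsistent with allele lengths")
  }
  if (!is.null(df$context3)) {
    df$context3 <- toupper(as.character(df$context3))
    df$context3[df$context3 %in% c("", "NA", ".")] <- NA_character_
    has_ctx <- !is.na(df$context3) & df$variant_type == "SNV"
    mid <- substr(df$context3[has_ctx], 2, 2)
    assert_that(all(mid == df$ref[has_ctx]),
                "context3 middle base must equal ref")
  }
  class(df) <- c("wex_mutations", "data.frame")
  df
}

#' Read an allele-specific copy-number segment table
#'
#' Segments are sorted by sample, chromosome and start; overlapping segments
#' within a sample/chromosome are rejected.
#'
#' @param path TSV with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cn_total`, `cn_minor`, and optionally `log2r`.
#' @return data.frame of class `wex_segments`.
#' @export
read_segment_table <- function(path) {
  df <- read_wex_tsv(path)
  require_columns(df, c("sample_id", "chrom", "start", "end",
                        "cn_total", "cn_minor"), "segment table")
  as_segments(df)
}

#' Validate and normalize a segment data.frame
#' @param df data.frame with the segment-table schema.
#' @return validated `wex_segments` data.frame, sorted within sample/chrom.
#' @export
as_segments <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  for (col in c("start", "end", "cn_total", "cn_minor"))
    df[[col]] <- as.numeric(df[[col]])
  assert_that(all(df$start <= df$end), "segment start must be <= end")
  assert_that(all(df$cn_minor >= 0 & df$cn_minor <= df$cn_total),
              "cn_minor must satisfy 0 <= cn_minor <= cn_total")
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$sample_id, df$chrom)
  for (k in unique(key)) {
    seg <- df[key == k, , drop = FALSE]
    if (nrow(seg) > 1) {
      bad <- which(seg$start[-1] <= seg$end[-nrow(seg)])
      assert_that(length(bad) == 0,
                  sprintf("overlapping segments in %s at start(s): %s", k,
                          paste(seg$start[bad + 1], collapse = ", ")))
    }
  }
  class(df) <- c("wex_segments", "data.frame")
  df
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `group` (IBC/nonIBC), `subtype`
#'   (HRpos_HER2neg/HER2pos/TN), `age`, `purity`, `ploidy`, `panel_size_mb`.
#' @return data.frame of class `wex_samples`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_wex_tsv(path)
  require_columns(df, c("sample_id", "group", "subtype", "age", "purity",
                        "ploidy", "panel_size_mb"), "sample sheet")
  as_samples(df)
}

#' Validate and normalize a sample sheet data.frame
#' @param df data.frame with the sample-sheet schema.
#' @return validated `wex_samples` data.frame.
#' @export
as_samples <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  assert_that(!anyDuplicated(df$sample_id),
              sprintf("duplicate sample_id: %s",
                      paste(unique(df$sample_id[duplicated(df$sample_id)]),
                            collapse = ", ")))
  df$group <- as.character(df$group)
  df$subtype <- as.character(df$subtype)
  bad_g <- setdiff(unique(df$group), GROUPS)
  assert_that(length(bad_g) == 0,
              sprintf("unknown group '%s'; allowed: %s",
                      paste(bad_g, collapse = ", "),
                      paste(GROUPS, collapse = ", ")))
  bad_s <- setdiff(unique(df$subtype), SUBTYPES)
  assert_that(length(bad_s) == 0,
              sprintf("unknown subtype '%s'; allowed: %s",
                      paste(bad_s, collapse = ", "),
                      paste(SUBTYPES, collapse = ", ")))
  for (col in c("age", "purity", "ploidy", "panel_size_mb"))
    df[[col]] <- as.numeric(df[[col]])
  assert_that(all(df$purity > 0 & df$purity <= 1), "purity must be in (0, 1]")
  assert_that(all(df$panel_size_mb > 0), "panel_size_mb must be > 0")
  class(df) <- c("wex_samples", "data.frame")
  df
}

#' Assemble and cross-validate a cohort dataset
#'
#' @param mutations `wex_mutations` data.frame.
#' @param segments `wex_segments` data.frame.
#' @param samples `wex_samples` data.frame.
#' @return list of class `wex_cohort` with elements `mutations`, `segments`,
#'   `samples`.
#' @export
cohort_dataset <- function(mutations, segments, samples) {
  mutations <- if (inherits(mutations, "wex_mutations")) mutations else as_mutations(mutations)
  segments <- if (inherits(segments, "wex_segments")) segments else as_segments(segments)
  samples <- if (inherits(samples, "wex_samples")) samples else as_samples(samples)
  orphans <- setdiff(c(unique(mutations$sample_id), unique(segments$sample_id)),
                     samples$sample_id)
  assert_that(length(orphans) == 0,
              sprintf("sample_id(s) absent from sample sheet: %s",
                      paste(orphans, collapse = ", ")))
  structure(list(mutations = mutations, segments = segments, samples = samples),
            class = "wex_cohort")
}

#' Write a cohort dataset to a directory as three TSVs
#' @param dataset `wex_cohort` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             segments = file.path(dir, "segments.tsv"),
             samples = file.path(dir, "samples.tsv"))
  write_wex_tsv(dataset$mutations, paths["mutations"])
  write_wex_tsv(dataset$segments, paths["segments"])
  write_wex_tsv(dataset$samples, paths["samples"])
  invisible(paths)
}

#' Read a cohort dataset written by [write_cohort()]
#' @param dir directory containing `mutations.tsv`, `segments.tsv`,
#'   `samples.tsv`.
#' @return `wex_cohort` object.
#' @export
read_cohort <- function(dir) {
  cohort_dataset(read_mutation_table(file.path(dir, "mutations.tsv")),
                 read_segment_table(file.path(dir, "segments.tsv")),
                 read_sample_sheet(file.path(dir, "samples.tsv")))
}

#' Read a gene model table
#' @param path TSV with columns `gene`, `chrom`, `start`, `end`.
#' @return data.frame with one row per gene.
#' @export
read_gene_model <- function(path) {
  gm <- read_wex_tsv(path)
  require_columns(gm, c("gene", "chrom", "start", "end"), "gene model table")
  gm$gene <- as.character(gm$gene)
  gm$chrom <- as.character(gm$chrom)
  gm$start <- as.numeric(gm$start)
  gm$end <- as.numeric(gm$end)
  assert_that(all(gm$start <= gm$end), "gene start must be <= end")
  assert_that(!anyDuplicated(gm$gene), "duplicated gene in gene model")
  gm
}

#' Bundled gene model for commonly assessed breast-cancer genes (hg19)
#' @return data.frame as from [read_gene_model()].
#' @export
load_default_gene_model <- function() {
  read_gene_model(wex_extdata("gene_model_hg19.tsv"))
}

#' Look up the trinucleotide reference context of a position
#'
#' Returns the uppercase forward-strand 3-mer centered on `pos`. Positions at
#' a chromosome edge (no flanking base) return `NA`; callers exclude those
#' records from spectra and log the count.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param reference Either a named character vector of chromosome sequences,
#'   or the path of a FASTA file (read via Biostrings when installed).
#' @return character 3-mer, or `NA_character_` when unavailable.
#' @export
trinucleotide_context <- function(chrom, pos, reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    assert_that(requireNamespace("Biostrings", quietly = TRUE),
                "Biostrings is required to read a FASTA reference",
                "wexscape_dependency_error")
    seqs <- Biostrings::readDNAStringSet(reference)
    reference <- stats::setNames(as.character(seqs),
                                 sub("\\s.*$", "", names(seqs)))
  }
  assert_that(chrom %in% names(reference),
              sprintf("chromosome '%s' absent from reference", chrom))
  seq <- reference[[chrom]]
  if (pos < 2 || pos > nchar(seq) - 1) return(NA_character_)
  toupper(substr(seq, pos - 1, pos + 1))
}
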