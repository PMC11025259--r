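#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so library functions that need
# reproducible draws do not clobber the caller's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_wex <- function(msg, class) {
  stop(structure(
    class = c(class, "wexscape_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "wexscape_validation_error") {
  if (!isTRUE(cond)) abort_wex(msg, class)
  invisible(TRUE)
}

# Cosine similarity between two nonnegative vectors; 0 if either is all-zero.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(strsplit(s, NULL), function(x)
    paste(rev(x), collapse = ""), character(1)))
}

wex_extdata <- function(file) {
  path <- system.file("extdata", file, package = "wexscape")
  assert_that(nzchar(path), sprintf("bundled data file '%s' not found", file),
              "wexscape_internal_error")
  path
}

read_wex_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_wex_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  assert_that(length(missing) == 0,
              sprintf("%s is missing required column(s): %s", what,
                      paste(missing, collapse = ", ")),
              "wexscape_schema_error")
}
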