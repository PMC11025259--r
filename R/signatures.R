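# Reference-signature refitting (NNLS), positivity calls, de-novo NMF
# extraction, and catalog matching on SBS-96 spectra.

profile_from_weights <- function(weights, background = 0.10) {
  channels <- sbs96_channels()
  p <- stats::setNames(rep(background / 96, 96), channels)
  p[names(weights)] <- p[names(weights)] + (1 - background) * weights / sum(weights)
  p / sum(p)
}

#' Bundled synthetic reference-signature catalog (30 x 96)
#'
#' A deterministic, synthetic stand-in for a 30-signature SBS-96 reference
#' catalog (the real COSMIC v2 matrix is licensed/distributed externally and
#' is not shipped). Signatures 1, 2, 3, 6, 10, 13, 20 and 26 are given
#' structured profiles reflecting their canonical shapes (CpG C>T for the
#' age-related signature, TpC C>T / C>G for the two APOBEC signatures, a
#' near-flat profile for the HRD signature, and so on); the remaining
#' signatures are seeded sparse simplex draws. Any user-supplied catalog in
#' the same channel order can be used instead via [read_signature_matrix()].
#'
#' @return numeric matrix, 96 rows (channels) x 30 columns (signatures
#'   `S1`..`S30`), each column summing to 1.
#' @export
reference_signatures <- function() {
  channels <- sbs96_channels()
  ch <- function(f5, sub, f3) as.vector(outer(f5, f3, function(a, b)
    paste0(a, "[", sub, "]", b)))
  structured <- list(
    # S1: age-related, C>T at NpCpG
    S1 = profile_from_weights(stats::setNames(rep(1, 4), ch(BASES, "C>T", "G")),
                              background = 0.25),
    # S2: APOBEC, C>T at TpCpW
    S2 = profile_from_weights(stats::setNames(c(1, 0.8), ch("T", "C>T", c("A", "T"))),
                              background = 0.15),
    # S3: HRD, near-flat
    S3 = profile_from_weights(stats::setNames(rep(1, 96), channels),
                              background = 0.0),
    # S6: mismatch repair, GpCpN C>T with some T>C
    S6 = profile_from_weights(stats::setNames(c(rep(1, 4), rep(0.35, 4)),
                                              c(ch("G", "C>T", BASES),
                                                ch("A", "T>C", BASES))),
                              background = 0.15),
    # S10: POLE, TpCpT C>A dominant
    S10 = profile_from_weights(stats::setNames(c(1, 0.25), c("T[C>A]T", "T[C>G]T")),
                               background = 0.10),
    # S13: APOBEC, C>G at TpCpW
    S13 = profile_from_weights(stats::setNames(c(1, 0.8), ch("T", "C>G", c("A", "T"))),
                               background = 0.15),
    # S20, S26: mismatch-repair related, mixed C>T / T>C shapes
    S20 = profile_from_weights(stats::setNames(c(rep(0.8, 4), rep(1, 4)),
                                               c(ch("C", "C>T", BASES),
                                                 ch("C", "T>C", BASES))),
                               background = 0.20),
    S26 = profile_from_weights(stats::setNames(rep(1, 16),
                                               ch(BASES, "T>C", BASES)),
                               background = 0.25))
  mat <- matrix(0, 96, 30, dimnames = list(channels, paste0("S", 1:30)))
  for (nm in names(structured)) mat[, nm] <- structured[[nm]]
  rest <- setdiff(colnames(mat), names(structured))
  draws <- with_seed(961, lapply(seq_along(rest), function(i) {
    w <- stats::rgamma(96, shape = 0.15)   # sparse Dirichlet(0.15) draw
    w / sum(w)
  }))
  for (i in seq_along(rest)) mat[, rest[i]] <- draws[[i]]
  mat
}

#' Read a signature catalog from TSV
#' @param path TSV whose first column holds the 96 channel names (canonical
#'   order not required; rows are reordered) and remaining columns one
#'   signature each.
#' @return numeric 96 x k matrix with columns normalized to sum 1.
#' @export
read_signature_matrix <- function(path) {
  df <- read_wex_tsv(path)
  channels <- sbs96_channels()
  assert_that(all(channels %in% df[[1]]),
              "signature table must contain all 96 SBS channels in column 1")
  m <- as.matrix(df[match(channels, df[[1]]), -1, drop = FALSE])
  rownames(m) <- channels
  storage.mode(m) <- "double"
  assert_that(all(m >= 0), "signature profiles must be nonnegative")
  sweep(m, 2, colSums(m), "/")
}

#' Refit a spectrum against a reference catalog
#'
#' Nonnegative least-squares fit of a 96-channel count vector against the
#' reference profiles (active-set NNLS on the raw counts), with exposures
#' normalized to fractions and the cosine similarity between the observed
#' and reconstructed spectra reported.
#'
#' @param spectrum `wex_spectrum96` or a numeric vector of 96 counts.
#' @param reference 96 x k signature matrix (columns sum to 1).
#' @return list of class `wex_exposure` with `weights` (named fractions
#'   summing to 1), `raw` (unnormalized NNLS coefficients),
#'   `reconstruction_cosine`, `sample_id`.
#' @export
refit_signatures <- function(spectrum, reference = reference_signatures()) {
  sample_id <- NA_character_
  if (inherits(spectrum, "wex_spectrum96")) {
    sample_id <- spectrum$sample_id
    spectrum <- spectrum$counts
  }
  assert_that(length(spectrum) == 96 && all(spectrum >= 0),
              "spectrum must be 96 nonnegative counts")
  assert_that(sum(spectrum) > 0, "cannot refit an all-zero spectrum")
  fit <- pracma::lsqnonneg(reference, as.numeric(spectrum))
  x <- fit$x
  recon <- as.numeric(reference %*% x)
  structure(list(sample_id = sample_id,
                 weights = stats::setNames(x / sum(x), colnames(reference)),
                 raw = stats::setNames(x, colnames(reference)),
                 reconstruction_cosine = cosine_sim(recon, as.numeric(spectrum))),
            class = "wex_exposure")
}

#' Signature positivity calls
#'
#' A sample is positive for a signature when its normalized exposure exceeds
#' the threshold (strict `>`, default 10%).
#'
#' @param exposure `wex_exposure` or a named numeric vector of fractions.
#' @param threshold positivity cutoff.
#' @return named logical vector.
#' @export
signature_positivity <- function(exposure, threshold = 0.10) {
  w <- if (inherits(exposure, "wex_exposure")) exposure$weights else exposure
  w > threshold
}

nmf_objective <- function(V, W, H) sum((V - W %*% H)^2)

nmf_once <- function(V, rank, max_iter, tol) {
  n <- ncol(V); p <- nrow(V)
  W <- matrix(stats::runif(p * rank, 0.1, 1), p, rank)
  H <- matrix(stats::runif(rank * n, 0.1, 1), rank, n)
  eps <- 1e-12
  obj <- nmf_objective(V, W, H)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0) {
      new_obj <- nmf_objective(V, W, H)
      if (abs(obj - new_obj) < tol * max(obj, eps)) { obj <- new_obj; break }
      obj <- new_obj
    }
  }
  list(W = W, H = H, objective = nmf_objective(V, W, H))
}

#' De-novo signature extraction by NMF
#'
#' Factorizes a nonnegative 96 x n spectra matrix as `V ~ W H` by
#' multiplicative updates minimizing squared Frobenius error, keeping the
#' best of `n_restarts` random restarts. Signature columns are normalized to
#' sum 1, with magnitudes absorbed into the exposures.
#'
#' @param spectra numeric 96 x n nonnegative matrix (samples in columns).
#' @param rank number of signatures to extract, in `[1, min(96, n)]`.
#' @param seed integer seed controlling the restarts.
#' @param n_restarts random restarts; the lowest-objective run is kept.
#' @param max_iter,tol update iteration controls.
#' @return list with `signatures` (96 x rank, columns sum to 1), `exposures`
#'   (rank x n), `objective`.
#' @export
extract_denovo_signatures <- function(spectra, rank, seed = 1, n_restarts = 5,
                                      max_iter = 2000, tol = 1e-8) {
  assert_that(all(spectra >= 0), "spectra matrix must be nonnegative")
  assert_that(rank >= 1 && rank <= min(nrow(spectra), ncol(spectra)),
              sprintf("rank must be in [1, %d]", min(nrow(spectra), ncol(spectra))))
  runs <- with_seed(seed, lapply(seq_len(n_restarts), function(r)
    nmf_once(spectra, rank, max_iter, tol)))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  rownames(W) <- rownames(spectra)
  colnames(W) <- paste0("SBS", LETTERS[seq_len(rank)])
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(spectra)
  list(signatures = W, exposures = H, objective = best$objective)
}

#' Match candidate signatures to a reference catalog by cosine similarity
#'
#' Each candidate is assigned its best-matching reference signature, or
#' `"unassigned"` when no reference reaches `min_cosine` — the state of a
#' novel signature with unknown etiology.
#'
#' @param candidate 96 x k matrix of candidate profiles.
#' @param reference 96 x m reference catalog in the same channel order.
#' @param min_cosine assignment threshold.
#' @return data.frame with columns `candidate`, `match`, `cosine`.
#' @export
match_signatures <- function(candidate, reference = reference_signatures(),
                             min_cosine = 0.8) {
  assert_that(is.null(rownames(candidate)) ||
                identical(rownames(candidate), rownames(reference)),
              "candidate and reference must share the same 96-bin order")
  out <- lapply(seq_len(ncol(candidate)), function(j) {
    sims <- apply(reference, 2, cosine_sim, b = candidate[, j])
    best <- which.max(sims)
    data.frame(candidate = colnames(candidate)[j] %||% paste0("C", j),
               match = if (sims[best] >= min_cosine) colnames(reference)[best]
                       else "unassigned",
               cosine = unname(sims[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Survey NMF ranks by reconstruction error and profile stability
#'
#' Fits each rank with two independent restart sets and reports the relative
#' Frobenius reconstruction error plus the mean cosine agreement between the
#' two runs' matched profiles — a simple stability diagnostic for choosing
#' the number of de-novo signatures.
#'
#' @param spectra numeric 96 x n matrix.
#' @param ranks integer vector of ranks to survey.
#' @param seed integer seed.
#' @param n_restarts restarts per fit.
#' @return data.frame with columns `rank`, `rel_error`, `stability`.
#' @export
nmf_rank_survey <- function(spectra, ranks = 2:8, seed = 1, n_restarts = 3) {
  norm_v <- sqrt(sum(spectra^2))
  do.call(rbind, lapply(ranks, function(r) {
    f1 <- extract_denovo_signatures(spectra, r, seed = seed,
                                    n_restarts = n_restarts)
    f2 <- extract_denovo_signatures(spectra, r, seed = seed + 10000,
                                    n_restarts = n_restarts)
    sims <- vapply(seq_len(r), function(j)
      max(apply(f2$signatures, 2, cosine_sim, b = f1$signatures[, j])),
      numeric(1))
    data.frame(rank = r, rel_error = sqrt(f1$objective) / norm_v,
               stability = mean(sims))
  }))
}

#' A seeded novel signature profile
#'
#' Draws a sparse random profile on the 96-simplex, deliberately unlike any
#' catalog signature; used to exercise the "unassigned" matching path.
#'
#' @param seed integer seed.
#' @param concentration Dirichlet concentration (smaller = sparser).
#' @return numeric vector of length 96 summing to 1.
#' @export
novel_signature_profile <- function(seed = 424, concentration = 0.05) {
  with_seed(seed, {
    w <- stats::rgamma(96, shape = concentration)
    stats::setNames(w / sum(w), sbs96_channels())
  })
}
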