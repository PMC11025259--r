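---
title: "Methods and models behind wexscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind wexscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

wexscape implements the downstream half of a tumor whole-exome study: it
starts where variant calling ends. Inputs are per-sample somatic mutation
tables (MAF-like), allele-specific copy-number segments (SEG-like, as
produced by tools such as FACETS), and a sample sheet carrying group
(IBC / non-IBC), immunohistochemistry subtype, age, purity, ploidy and panel
size. From these it computes mutation burden and class accounting, SBS-96
mutational spectra with signature refitting and de-novo extraction,
genomic-scar HRD scores, cancer-cell-fraction based clonality and intratumor
heterogeneity, gene-level copy-number alteration frequencies, actionability
tiers, and subtype-adjusted two-cohort comparisons.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.
It states no empirical result beyond what the package's tests and the
acceptance script themselves compute.

## Coordinates and input contracts

All on-disk coordinates are 1-based closed intervals, the MAF/SEG
convention; segment length is `end - start + 1`. Validation is total:
malformed input raises a typed condition (`wexscape_schema_error`,
`wexscape_parse_error`, `wexscape_validation_error`) rather than silently
dropping rows. The only silent-ish path is context-unavailable SNVs in
spectra, which are excluded with an exclusion count so that binned counts
plus exclusions always equal the SNV total.

Mutation tables may carry a precomputed `context3` column so no reference
FASTA is needed; FASTA lookup (via Biostrings) is the fallback. Variant
classification accepts common MAF vocabulary (`Missense_Mutation`,
`Frame_Shift_Del`, ...) through an explicit synonym table; unmapped labels
become `other` with a warning.

## Mutation burden

TMB is the count of coding mutations — missense, nonsense, silent, plus all
indels — divided by the capture territory in Mb, with a high-TMB flag above
10 mutations/Mb (strict `>`). The panel size has no default: it is a
property of the capture kit, so `pipeline_config()` requires it. The
package's own simulations use 38 Mb, a typical whole-exome capture
territory. Class fractions follow the conventions used in cohort
comparisons: the non-silent fraction is taken over all mutations, while
missense/nonsense fractions are taken among non-silent SNVs only.

## Mutational spectra and signatures

Spectra use the pyrimidine-centric 96-channel convention: substitutions
C>A, C>G, C>T, T>A, T>C, T>G crossed with 5' and 3' bases, ordered
substitution-major then lexicographic (`A[C>A]A` ... `T[T>G]T`).
Purine-reference SNVs are reverse-complemented before binning.

Refitting solves a nonnegative least-squares problem on the raw 96-count
vector against a reference catalog (active-set NNLS via
`pracma::lsqnonneg`), then normalizes exposures to fractions and reports
the cosine similarity between observed and reconstructed spectra.
Refitting is per sample, not cohort-pooled, so stacked per-sample exposure
plots are directly available. Per-signature positivity uses a strict 10%
exposure threshold. Whether a refit should be restricted to a
tissue-specific subset of signatures is left to the caller: the default is
the full catalog, and `refit_signatures()` accepts any column subset.

The bundled 30-signature catalog is a deterministic *synthetic* stand-in
(`reference_signatures()`): the real COSMIC v2 matrix is distributed under
its own terms and is not shipped. Eight signatures that matter for breast
cohorts (1, 2, 3, 6, 10, 13, 20, 26) are given structured profiles
matching their canonical shapes — CpG-context C>T for the age-related
signature, TpC-context C>T and C>G for the two APOBEC signatures, a
near-flat profile for the HRD signature, a dominant TpCpT C>A peak for
POLE — and the remainder are seeded sparse simplex draws. Every algorithm
is agnostic to the catalog; a real catalog in the same channel order drops
in via `read_signature_matrix()`.

De-novo extraction is multiplicative-update NMF minimizing squared
Frobenius error, best of `n_restarts` random restarts, with signature
columns normalized to sum 1 and magnitudes absorbed into exposures. The
rank is a parameter; `nmf_rank_survey()` reports reconstruction error and
between-run profile stability for candidate ranks, since no single
selection rule is canonical. Candidate signatures are matched to the
catalog by cosine similarity with an assignment floor of 0.8; profiles
below the floor are reported `unassigned`, the state of a novel signature
of unknown etiology.

## Genomic-scar HRD score

Segments are preprocessed per sample: split at the centromere (the
centromeric interval is discarded), segments shorter than 3 Mb removed,
and adjacent segments with identical `(cn_total, cn_minor)` merged until
stable. The three components then are:

* **LOH**: segments with minor copy number 0 and total copy number at
  least 1, longer than 15 Mb (strict), excluding chromosomes in
  whole-chromosome LOH.
* **TAI**: allelically imbalanced segments (major != minor, with
  major = total - minor) whose outer boundary lies within 1 kb of a
  telomere, not crossing the centromere, at least 11 Mb long.
* **LST**: per-arm breakpoints between adjacent segments with different
  copy-number state, both at least 10 Mb, separated by less than 3 Mb.

HRD = LOH + TAI + LST, with the HRD-high flag at >= 42 (inclusive). All
four sizes (15 / 11 / 10 / 3 Mb) and the cutoff are configurable, because
the literature varies in the details — notably whether TAI carries a
minimum size and whether LST is counted per arm or per chromosome. The
package counts LST per arm, uses an 11 Mb TAI minimum, and documents both
as defaults rather than universals. The 1 kb telomere tolerance reflects
that exome-derived segments rarely reach the literal chromosome end.

## Gene-level CNA calls

Each gene in the gene model receives the log2 ratio of its
maximally-overlapping segment (ties resolved toward the larger absolute
ratio), derived as `log2(cn_total / 2)` when the segment table carries no
ratio column (total copy number is floored at 0.25 copies so homozygous
deletions map to a finite, strongly negative value). Calls use strict
thresholds: gain above 0.2, amplification above 0.9, loss below -0.2,
deletion below -0.9; exactly 0.2 is neutral, exactly 0.9 is gain. Genes
with no overlapping segment are neutral with a missing-value flag.
Recurrence is expressed as per-gene alteration frequencies by group, fed
into per-gene Fisher tests with BH correction; peak-based significance
calling (GISTIC-style) is deliberately out of scope.

## Clonality and heterogeneity

For a mutation at multiplicity $m$ on total copy number $n_t$ in a tumor
of purity $p$:

$$\mathrm{VAF} = \frac{\mathrm{CCF} \cdot p \cdot m}{p\,n_t + 2(1-p)}$$

Multiplicity is estimated by rounding the corrected allele fraction and
clamping to $[1, n_t]$; the CCF point estimate is capped at 2 for
reporting. The VAF posterior is Beta(alt + 1, ref + 1) — a uniform prior,
chosen in the absence of any stated alternative — and its highest density
interval (narrowest interval at the chosen level, default 95%) is mapped
through the linear VAF-to-CCF transform. A mutation is Clonal when CCF = 1
falls inside the interval. Intervals lying entirely above 1, an artifact
of integer multiplicity rounding, are also called Clonal by default: the
literal containment rule would label them Subclonal, which is biologically
implausible for an over-estimated multiplicity; `strict = TRUE` restores
the literal rule. Mutations below a depth floor (default 8 reads) or on
homozygous-deletion sites are excluded with logged counts.

Clonal architecture per sample is a 1-D Gaussian mixture on CCF fit by EM
for k = 1..6 with BIC selection (via mclust), restricted by default to
copy-number-neutral sites where the CCF transform is most reliable.
Clusters holding under 2% of mutations are dropped and proportions
renormalized. Values are sorted before fitting so the solution is
invariant to input order. Samples with fewer than 10 eligible mutations
are flagged not assessable. The Shannon index $H = -\sum p_i \ln p_i$
(natural log) over cluster proportions, with heterogeneity declared at
H > 1, summarizes the architecture; note that with natural logs three
equal clusters sit just above the cutoff ($\ln 3 \approx 1.10$) and two
equal clusters below it ($\ln 2 \approx 0.69$). No claim of equivalence
with variational beta-mixture clustering tools (SciClone and kin) is made;
the BIC-selected Gaussian mixture is this package's own, simpler choice.

## Actionability

A frozen mini knowledge base ships with the package covering the
alteration classes most relevant in breast cancer (ERBB2 amplification and
PIK3CA hotspots at OncoKB level 1 / ESCAT I; BRCA1/2 mutation or deletion;
PTEN deletion and AKT1 E17K / ESR1 hotspots at ESCAT II, among others).
Mutations match `mutation` entries by gene, never when silent, and only on
the listed protein changes when the entry carries a hotspot filter; CNA
entries match amplification/deletion calls exactly. Summaries report, per
sample and per group, any-AGA, OncoKB LOE 1-2, LOE 3-4, ESCAT I-II, and
multi-AGA flags. The KB format is open for user-supplied catalogs; no live
database queries are made.

## Two-cohort statistics

Continuous features use the Wilcoxon rank-sum test (exact when the pooled
n is at most 20 without ties, normal approximation with tie correction
otherwise) with median (range) summaries; binary features use Fisher's
exact test (two-sided by summing hypergeometric probabilities at most as
likely as the observed table; conditional-MLE odds ratio) with n (%)
summaries. Subtype/age adjustment fits a binomial logit model of the group
indicator on the feature plus covariates, reporting the Wald p-value and
OR per feature unit; Wald rather than likelihood-ratio p-values are used
and labeled as such. Complete separation is flagged unreliable instead of
silently reported. FDR control is Benjamini-Hochberg, applied separately
per family (per-gene mutation frequencies, per-gene CNAs, signature
positivity) so that each family's correction is explicit. Features
constant across the cohort are reported with p = 1 rather than erroring
mid-pipeline.

## The synthetic cohort generator

`simulate_cohort()` emulates every structure the pipeline assumes, with
known ground truth: negative-binomial per-sample mutation counts (long
right tail; default mean 80, dispersion 1.3, floor 10), subtype mixes with
more HER2+ and TN disease in the IBC group, signature mixtures with an
age-related-signature excess in the non-IBC group, log-normal sequencing
depth around 180x, uniform purity on [0.6, 0.95], one-cluster versus
three-equal-cluster clonal architectures (heterogeneous archetype
probability 21% in IBC vs 33% in non-IBC), and Poisson-distributed scar
targets from a low or high archetype whose high-archetype probability is
largest in TN IBC samples. Trinucleotide contexts are sampled directly
from the mixed signature profile and emitted in the table, so no genome
walk or FASTA is needed.

Scar-bearing segment profiles are *constructed from the scoring
definitions' geometry*, not by calling the scorer: LOH chains are 20 Mb
(1,0) segments isolated by 9 Mb balanced (4,2) buffers (too short to
create LST breakpoints, balanced so they create no TAI); TAI events are
15 Mb imbalanced telomeric segments; LST events are 12 Mb balanced blocks
flanked by >= 10 Mb diploid filler. Focal gene events (ERBB2
amplification, BRCA1/2 and PTEN deletions) are placed on four reserved
chromosomes that scar events avoid, and are sized below 10 Mb so they
contribute no scar counts — gene calls and scar counts stay independently
controlled, and scorer-versus-generator tests are a genuine dual route.

What the generator does **not** emulate: sequencing artifacts and strand
bias, subclonal copy number, mutation multiplicity above 1, germline
contamination, kataegis/clustered mutations, and real genomic position
effects (positions are uniform over diploid segments). Passing parameter-
recovery tests therefore demonstrates algorithmic correctness under the
model's assumptions, not robustness to everything real exomes contain.

## Numerical choices and degenerate inputs

* Beta HDI: the narrowest interval is found by minimizing width over the
  lower tail probability with `stats::optimize`; shape parameters at or
  below 1 fall back to one-sided or central intervals.
* NNLS ties and NMF restarts: the lowest-objective restart wins; NMF
  convergence is declared on a relative objective change below 1e-8
  checked every 10 iterations.
* CNA overlap ties go to the segment with the larger absolute log2 ratio.
* Empty samples yield zero counts with NA fractions; empty cohorts are
  valid datasets; single-group cohorts skip comparison stages with an
  explicit notice.
* Problem sizes in the test-suite and acceptance runs — 24 samples per
  group for the default cohort, 40 samples x 2000 mutations for NMF
  recovery, 1000 mutations for interval calibration, 500 replicates at
  n = 400 for the logistic null — were chosen as the smallest sizes at
  which the corresponding statistical properties are stable.

## Known limitations

No structural variants or fusions, no indel/doublet signature classes, no
multi-sample phylogenies or mutation timing, no neoantigen analysis, no
survival modeling, and no re-implementation of segmentation, purity
estimation, or peak-based CNA significance — segments and purity are
inputs, and recurrence comparison is frequency-based. The bundled
reference catalog, driver list, and knowledge base are deliberately small,
frozen, and replaceable.
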