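# Two-cohort comparison layer: Wilcoxon rank-sum, Fisher's exact test with
# conditional-MLE odds ratio, logistic (logit-link) covariate adjustment on
# molecular subtype and/or age, and Benjamini-Hochberg FDR control.
# The tests delegate to stats::wilcox.test / fisher.test / glm / p.adjust;
# this layer fixes conventions (exactness rules, two-sided definitions,
# summaries) and assembles uniform result records.

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p-value when the pooled sample size is at most 20 and
#' there are no ties; normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `statistic` (rank-sum W), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of tables at
#' most as probable as the observed one; odds ratio by conditional maximum
#' likelihood. Table layout: rows are `(a, b)` and `(c, d)`.
#'
#' @param a,b,c,d nonnegative integer cell counts; every margin must be > 0.
#' @return list with `odds_ratio`, `p_value`, `table`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  assert_that(all(cells >= 0) && all(cells == round(cells)),
              "cells must be nonnegative integers")
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "every margin of the 2x2 table must be positive")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Subtype/age-adjusted group comparison via a logistic model
#'
#' Regresses the group indicator (IBC = 1) on the feature plus covariate
#' terms with a binomial logit link. Reports the Wald p-value and the odds
#' ratio per feature unit. Complete or quasi-complete separation is flagged
#' (`reliable = FALSE`) rather than silently reported.
#'
#' @param group character/factor of group labels (`"IBC"` / `"nonIBC"`).
#' @param feature numeric (or logical) per-sample feature.
#' @param subtype optional molecular-subtype covariate.
#' @param age optional age covariate.
#' @return list with `odds_ratio`, `coefficient`, `p_value`, `reliable`.
#' @export
logit_adjusted <- function(group, feature, subtype = NULL, age = NULL) {
  y <- as.integer(group == "IBC")
  assert_that(length(unique(y)) == 2, "both groups must be present")
  df <- data.frame(y = y, feature = as.numeric(feature))
  form <- "y ~ feature"
  if (!is.null(subtype)) {
    assert_that(length(unique(subtype)) >= 2,
                "subtype adjustment needs >= 2 subtype levels")
    df$subtype <- factor(subtype)
    form <- paste(form, "+ subtype")
  }
  if (!is.null(age)) {
    df$age <- as.numeric(age)
    form <- paste(form, "+ age")
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(form), family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  beta <- sm["feature", "Estimate"]
  p <- sm["feature", "Pr(>|z|)"]
  reliable <- !separated && abs(beta) < 15
  list(odds_ratio = exp(beta), coefficient = beta, p_value = p,
       reliable = reliable)
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return numeric vector of step-up q-values (monotone in the p-value
#'   ranks).
#' @export
bh_fdr <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Compare one per-sample feature between the two groups
#'
#' Continuous features go to the Wilcoxon rank-sum test with median (range)
#' summaries; binary features go to Fisher's exact test with n (%)
#' summaries. When `adjust` names covariates (`"subtype"`, `"age"`), a
#' logit-link adjusted model is fit as well.
#'
#' @param values per-sample feature values (numeric, or logical for
#'   `kind = "binary"`).
#' @param group per-sample group labels.
#' @param kind `"continuous"` or `"binary"`.
#' @param subtype,age optional per-sample covariates for adjustment.
#' @param adjust character subset of `c("subtype", "age")`.
#' @param feature name carried into the result.
#' @return one-row data.frame of class `wex_comparison`: feature, test,
#'   group summaries, `statistic`, `odds_ratio`, `p_value`, and adjusted
#'   `adj_odds_ratio`/`adj_p_value` when requested.
#' @export
compare_feature <- function(values, group, kind = c("continuous", "binary"),
                            subtype = NULL, age = NULL, adjust = character(0),
                            feature = "feature") {
  kind <- match.arg(kind)
  ok <- !is.na(values)
  assert_that(any(ok & group == "IBC") && any(ok & group == "nonIBC"),
              sprintf("feature '%s' is missing for an entire group", feature))
  v <- values[ok]; g <- group[ok]
  summarize_group <- function(gr) {
    vi <- v[g == gr]
    if (kind == "continuous")
      sprintf("%.3g (%.3g-%.3g)", stats::median(vi), min(vi), max(vi))
    else sprintf("%d/%d (%.0f%%)", sum(vi), length(vi), 100 * mean(vi))
  }
  if (kind == "continuous") {
    t <- wilcoxon_rank_sum(v[g == "IBC"], v[g == "nonIBC"])
    res <- data.frame(feature = feature, test = "wilcoxon",
                      summary_IBC = summarize_group("IBC"),
                      summary_nonIBC = summarize_group("nonIBC"),
                      statistic = t$statistic, odds_ratio = NA_real_,
                      p_value = t$p_value, stringsAsFactors = FALSE)
  } else if (all(v) || !any(v)) {
    # a feature constant across the cohort carries no group information
    res <- data.frame(feature = feature, test = "fisher",
                      summary_IBC = summarize_group("IBC"),
                      summary_nonIBC = summarize_group("nonIBC"),
                      statistic = NA_real_, odds_ratio = NA_real_,
                      p_value = 1, stringsAsFactors = FALSE)
  } else {
    v <- as.logical(v)
    t <- fisher_exact(sum(v[g == "IBC"]), sum(!v[g == "IBC"]),
                      sum(v[g == "nonIBC"]), sum(!v[g == "nonIBC"]))
    res <- data.frame(feature = feature, test = "fisher",
                      summary_IBC = summarize_group("IBC"),
                      summary_nonIBC = summarize_group("nonIBC"),
                      statistic = NA_real_, odds_ratio = t$odds_ratio,
                      p_value = t$p_value, stringsAsFactors = FALSE)
  }
  res$adj_odds_ratio <- NA_real_
  res$adj_p_value <- NA_real_
  res$adj_reliable <- NA
  if (length(adjust) > 0 && length(unique(v)) > 1) {
    la <- logit_adjusted(
      g, as.numeric(v),
      subtype = if ("subtype" %in% adjust) subtype[ok] else NULL,
      age = if ("age" %in% adjust) age[ok] else NULL)
    res$adj_odds_ratio <- la$odds_ratio
    res$adj_p_value <- la$p_value
    res$adj_reliable <- la$reliable
  }
  class(res) <- c("wex_comparison", "data.frame")
  res
}

#' Compare a family of features and apply FDR correction
#'
#' Runs [compare_feature()] for every column of `feature_table`, then
#' attaches Benjamini-Hochberg q-values computed across the family.
#'
#' @param feature_table data.frame of per-sample features (rows = samples).
#' @param group,kind,subtype,age,adjust as in [compare_feature()].
#' @return data.frame with one row per feature plus a `q_value` column.
#' @export
compare_features <- function(feature_table, group, kind = "continuous",
                             subtype = NULL, age = NULL,
                             adjust = character(0)) {
  rows <- lapply(names(feature_table), function(f)
    compare_feature(feature_table[[f]], group, kind = kind, subtype = subtype,
                    age = age, adjust = adjust, feature = f))
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}
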