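
#' Subtype enrichment of a risk group (hypergeometric test, odds ratio)
#'
#' Collapses risk group x subtype to a 2x2 table (target subtype vs all
#' others, unlabelled samples excluded) and reports the cross-product odds
#' ratio (Haldane-Anscombe +0.5 correction when any cell is zero) and the
#' one-sided hypergeometric tail probability `P(X >= observed)` of seeing at
#' least that many target-subtype samples in the high-risk group under random
#' assignment with fixed margins.
#'
#' @param groups Vector with levels `"high"`/`"low"`.
#' @param subtypes Subtype labels aligned with `groups` (`NOLBL`/`NA`
#'   excluded).
#' @param target Target subtype (default the mesenchymal poor-prognosis
#'   `"CMS4"`).
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return Tibble `odds_ratio`, `p`, plus the collapsed counts; the 2x2
#'   table is attached as attribute `table`.
#' @export
subtype_enrichment <- function(groups, subtypes, target = "CMS4",
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(groups) == length(subtypes))
  keep <- !is.na(subtypes) & subtypes != "NOLBL"
  groups <- groups[keep]
  subtypes <- subtypes[keep]
  if (!any(groups == "high") || !any(groups == "low")) {
    abort("Both risk groups must be non-empty after excluding unlabelled samples.")
  }
  if (!any(subtypes == target)) abort(glue("Target subtype '{target}' not present."))
  a <- sum(groups == "high" & subtypes == target)
  b <- sum(groups == "high" & subtypes != target)
  cc <- sum(groups == "low" & subtypes == target)
  d <- sum(groups == "low" & subtypes != target)
  tab <- matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE,
                dimnames = list(c("high", "low"), c(target, "other")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    abort("Zero margin in the collapsed 2x2 table.")
  }
  cells <- c(a, b, cc, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  # X ~ Hypergeometric(total target, total other, high-group size)
  p_upper <- phyper(a - 1L, a + cc, b + d, a + b, lower.tail = FALSE)
  p <- if (alternative == "greater") {
    p_upper
  } else {
    min(1, 2 * min(p_upper, phyper(a, a + cc, b + d, a + b)))
  }
  out <- tibble(odds_ratio = or, p = p, high_target = a, high_other = b,
                low_target = cc, low_other = d)
  attr(out, "table") <- tab
  out
}

#' Wilcoxon rank-sum comparison of a continuous variable between two groups
#'
#' Exact enumeration when both groups have at most 8 observations and there
#' are no ties; otherwise the normal approximation with midranks and tie
#' correction (no continuity correction).
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector aligned with `values`.
#' @return Tibble `statistic` (rank-sum W of the first level), `p`,
#'   `method`.
#' @export
compare_groups_continuous <- function(values, groups) {
  grp <- factor(groups)
  if (nlevels(grp) != 2L || any(table(grp) == 0L)) {
    abort("Need exactly 2 non-empty groups.")
  }
  x <- values[grp == levels(grp)[1L]]
  y <- values[grp == levels(grp)[2L]]
  has_ties <- anyDuplicated(values) > 0L
  exact <- length(x) <= 8L && length(y) <= 8L && !has_ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  tibble(statistic = unname(ht$statistic), p = ht$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Chi-square or Fisher's exact test for a 2xC contingency table
#'
#' Pearson chi-square without continuity correction when every expected
#' count is at least 5; otherwise Fisher's exact test (2x2 tables only).
#'
#' @param table Matrix of non-negative integer counts with >= 2 rows and
#'   columns.
#' @return Tibble `method`, `statistic` (chi-square only), `df`, `p`.
#' @export
compare_groups_categorical <- function(table) {
  if (!is.matrix(table) || nrow(table) < 2L || ncol(table) < 2L) {
    abort("Need a counts matrix with at least 2 rows and 2 columns.")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be non-negative integers.")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(expected >= 5)) {
    ht <- chisq.test(table, correct = FALSE)
    return(tibble(method = "chi-square", statistic = unname(ht$statistic),
                  df = unname(ht$parameter), p = ht$p.value))
  }
  if (!all(dim(table) == c(2L, 2L))) {
    abort("Expected counts below 5 in a table larger than 2x2; Fisher routing is 2x2 only.")
  }
  ht <- fisher.test(table)
  tibble(method = "fisher", statistic = NA_real_, df = NA_integer_, p = ht$p.value)
}

#' Immune-cell infiltration scores and group contrasts
#'
#' ssGSEA scores (normalization off: scores are compared within-sample
#' across groups) for each immune-cell gene program, then a Wilcoxon
#' rank-sum contrast high vs low risk per cell type with Benjamini-Hochberg
#' adjustment across cell types.
#'
#' @param expr Genes x samples expression matrix.
#' @param immune_sets A `gene_sets` collection of immune-cell programs.
#' @param groups `"high"`/`"low"` vector aligned with the samples.
#' @param alpha ssGSEA weight exponent.
#' @return List with `scores` (samples x cell types) and `contrasts` tibble
#'   (`cell_type`, `statistic`, `p`, `q`, `direction`).
#' @export
immune_infiltration <- function(expr, immune_sets, groups, alpha = 0.25) {
  if (length(groups) != ncol(expr)) abort("`groups` must align with the samples.")
  scores <- ssgsea_spectra(expr, immune_sets, alpha = alpha, normalize = FALSE)
  contrasts <- purrr::map_dfr(colnames(scores), function(ct) {
    res <- compare_groups_continuous(scores[, ct], groups)
    hi <- mean(scores[groups == "high", ct])
    lo <- mean(scores[groups == "low", ct])
    tibble(cell_type = ct, statistic = res$statistic, p = res$p,
           direction = if (hi >= lo) "higher in high-risk" else "higher in low-risk")
  })
  contrasts$q <- p.adjust(contrasts$p, method = "BH")
  list(scores = scores, contrasts = contrasts[, c("cell_type", "statistic",
                                                  "p", "q", "direction")])
}

#' Feature-versus-pathway Pearson correlation map
#'
#' Pearson r, two-sided p and BH-adjusted q for every (feature, pathway)
#' pair. Zero-variance columns are flagged and excluded from testing.
#'
#' @param features Samples x features matrix (e.g. radiomic features).
#' @param pathway_scores Samples x pathways matrix (e.g. enrichment scores).
#' @return A `correlation_map` tibble (`feature_id`, `pathway`, `r`, `p`,
#'   `q`) with flagged column ids in attribute `flagged`.
#' @export
pathway_feature_correlation <- function(features, pathway_scores) {
  if (nrow(features) != nrow(pathway_scores)) {
    abort("Sample mismatch between `features` and `pathway_scores`.")
  }
  if (nrow(features) < 3L) abort("Need at least 3 samples per pair.")
  flag_f <- colnames(features)[apply(features, 2L, sd) < 1e-12]
  flag_p <- colnames(pathway_scores)[apply(pathway_scores, 2L, sd) < 1e-12]
  fs <- setdiff(colnames(features), flag_f)
  ps <- setdiff(colnames(pathway_scores), flag_p)
  if (length(fs) == 0L || length(ps) == 0L) abort("No testable pairs.")
  grid <- tidyr::expand_grid(feature_id = fs, pathway = ps)
  res <- purrr::pmap_dfr(grid, function(feature_id, pathway) {
    ht <- cor.test(features[, feature_id], pathway_scores[, pathway],
                   method = "pearson")
    tibble(feature_id = feature_id, pathway = pathway,
           r = unname(ht$estimate), p = ht$p.value)
  })
  res$q <- p.adjust(res$p, method = "BH")
  structure(res, flagged = c(flag_f, flag_p),
            class = c("correlation_map", class(res)))
}
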