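
#' Median absolute deviation (unscaled)
#'
#' `median(|x - median(x)|)` with no consistency factor: the pipeline uses
#' MAD purely to rank candidate features by variability, where scaling is
#' irrelevant.
#'
#' @param values Numeric vector (>= 1 value).
#' @return Non-negative scalar.
#' @export
feature_mad <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    abort("`values` must be a non-empty numeric vector without NAs.")
  }
  median(abs(values - median(values)))
}

#' Correlate raw features with deep features
#'
#' Pearson correlation of every raw feature (gene or radiomic) against every
#' deep-feature column. Zero-variance features get correlation 0 and are
#' flagged; they never enter signature candidacy.
#'
#' @param raw Samples x features numeric matrix (e.g. `t(expr)`).
#' @param deep Samples x K deep-feature matrix from
#'   [extract_deep_features()].
#' @return Features x K correlation matrix with attribute `flagged` (ids of
#'   zero-variance features).
#' @export
correlate_features <- function(raw, deep) {
  if (!is.matrix(raw) || is.null(colnames(raw))) {
    abort("`raw` must be a samples x features matrix with feature column names.")
  }
  if (nrow(raw) != nrow(deep)) abort("Sample mismatch between `raw` and `deep`.")
  if (nrow(raw) < 3L) abort("Correlation needs at least 3 samples.")
  sds <- apply(raw, 2L, sd)
  flagged <- colnames(raw)[sds < 1e-12]
  cc <- suppressWarnings(cor(raw, deep))
  cc[!is.finite(cc)] <- 0
  cc[flagged, ] <- 0
  # numerical safety: |r| can exceed 1 by float error only
  cc <- pmin(pmax(cc, -1), 1)
  colnames(cc) <- colnames(deep)
  attr(cc, "flagged") <- flagged
  cc
}

#' Distill a compact signature from deep-feature correlations
#'
#' The translation step: per deep feature, features are ranked by absolute
#' correlation (descending, ties by feature id), the top `n_top` candidates
#' are re-ranked by MAD of their raw values (descending, ties by feature id),
#' and the top `n_keep` are retained. The union across deep features is
#' deduplicated by first occurrence, so the signature never exceeds
#' `K * n_keep` features.
#'
#' @param corr Features x K correlation matrix from [correlate_features()].
#' @param raw The samples x features matrix the correlations came from (MAD
#'   is computed on these raw values).
#' @param n_top Candidates per deep feature ranked by `|r|`.
#' @param n_keep Features kept per deep feature after MAD ranking.
#' @param modality `"gene"` or `"radiomic"`, recorded on the signature.
#' @return A `cms_signature` tibble: `feature_id`, `deep_feature`, `r`,
#'   `sign`, `mad`, in selection order.
#' @export
select_signature <- function(corr, raw, n_top = 10L, n_keep = 3L,
                             modality = c("gene", "radiomic")) {
  modality <- match.arg(modality)
  n_top <- check_count(n_top, "n_top")
  n_keep <- check_count(n_keep, "n_keep")
  if (n_keep > n_top) abort("`n_keep` must not exceed `n_top`.")
  flagged <- attr(corr, "flagged") %||% character()
  usable <- setdiff(rownames(corr), flagged)
  if (length(usable) < n_top) {
    abort(glue("Only {length(usable)} non-degenerate features; need n_top = {n_top}."))
  }
  mads <- apply(raw[, usable, drop = FALSE], 2L, feature_mad)
  picked <- list()
  for (k in seq_len(ncol(corr))) {
    r_k <- corr[usable, k]
    cand_ord <- order(-abs(r_k), usable)
    cand <- usable[cand_ord][seq_len(n_top)]
    keep_ord <- order(-mads[cand], cand)
    kept <- cand[keep_ord][seq_len(n_keep)]
    picked[[k]] <- tibble(
      feature_id = kept,
      deep_feature = colnames(corr)[k] %||% paste0("DF", k),
      r = unname(r_k[kept]),
      sign = unname(ifelse(r_k[kept] >= 0, "positive", "negative")),
      mad = unname(mads[kept])
    )
  }
  out <- dplyr::distinct(dplyr::bind_rows(picked), .data$feature_id, .keep_all = TRUE)
  structure(out, modality = modality, n_top = n_top, n_keep = n_keep,
            class = c("cms_signature", class(out)))
}

#' @export
print.cms_signature <- function(x, ...) {
  cat(glue("<cms_signature> {nrow(x)} {attr(x, 'modality')} feature(s)"), "\n")
  NextMethod()
}
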