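
#' Per-sample descending expression ranks
#'
#' Within each sample, genes are ranked by expression in descending order
#' (rank 1 = highest). Ties are broken by the stable order of the gene ids in
#' the matrix, so the result is always a permutation of `1..G`.
#'
#' @param expr Genes x samples expression matrix.
#' @return Integer matrix of the same shape holding each gene's rank within
#'   its sample.
#' @export
rank_transform <- function(expr) {
  expr <- as_expression_matrix(expr)
  g <- nrow(expr)
  out <- matrix(0L, nrow = g, ncol = ncol(expr), dimnames = dimnames(expr))
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], seq_len(g))  # descending value, stable by gene order
    out[ord, j] <- seq_len(g)
  }
  out
}

#' Single-sample gene set enrichment spectra (ssGSEA)
#'
#' For each sample, genes are ranked by expression in descending order. The
#' enrichment score of a set is the integrated difference between the
#' weighted in-set cumulative distribution (weights
#' `|rank value|^alpha` over in-set genes, normalized to sum 1, where the
#' rank value of the gene at descending position `p` among `G` genes is
#' `G - p + 1`) and the unweighted out-of-set cumulative distribution,
#' summed over all list positions. With `normalize = TRUE` all scores are
#' divided by the global `max - min` so the spectra span a unit range.
#'
#' Set members absent from the matrix are dropped per set; sets reduced below
#' an overlap of 2 genes, or covering every gene (empty complement), are
#' dropped with a warning. If no set survives, this is an error.
#'
#' @param expr Genes x samples expression matrix (log scale; ranks are taken
#'   on the supplied values as-is).
#' @param sets A `gene_sets` collection.
#' @param alpha Non-negative rank-weight exponent (0 = rank-only regime).
#' @param normalize Divide all scores by the global score range.
#' @return A `functional_spectra` samples x sets numeric matrix with
#'   attributes `alpha`, `normalized` and `dropped_sets`.
#' @export
ssgsea_spectra <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  expr <- as_expression_matrix(expr)
  stopifnot(inherits(sets, "gene_sets"))
  check_scalar_number(alpha, "alpha", min = 0)
  g <- nrow(expr)
  idx_sets <- lapply(sets, function(s) which(rownames(expr) %in% s))
  sizes <- lengths(idx_sets)
  keep <- sizes >= 2L & sizes < g
  dropped <- names(sets)[!keep]
  if (length(dropped) > 0L) {
    warn(glue(
      "Dropped {length(dropped)} gene set(s) with overlap < 2 or empty ",
      "complement: {paste(head(dropped, 5L), collapse = ', ')}."
    ))
  }
  idx_sets <- idx_sets[keep]
  if (length(idx_sets) == 0L) abort("All gene sets were dropped after overlap filtering.")

  scores <- matrix(
    0, nrow = ncol(expr), ncol = length(idx_sets),
    dimnames = list(colnames(expr), names(idx_sets))
  )
  total_tail <- g * (g + 1) / 2  # sum over all positions of (G - p + 1)
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], seq_len(g))
    pos <- integer(g)
    pos[ord] <- seq_len(g)
    tail_len <- g - pos + 1          # number of positions a gene contributes to
    w_all <- tail_len^alpha          # |rank value|^alpha, value at pos p is G-p+1
    for (s in seq_along(idx_sets)) {
      gs <- idx_sets[[s]]
      w <- w_all[gs]
      in_term <- sum(tail_len[gs] * w) / sum(w)
      out_term <- (total_tail - sum(tail_len[gs])) / (g - length(gs))
      scores[j, s] <- in_term - out_term
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, alpha = alpha, normalized = normalize,
            dropped_sets = dropped, class = c("functional_spectra", "matrix", "array"))
}

#' Spectra as a tibble
#'
#' @param x A `functional_spectra` matrix.
#' @param ... Unused.
#' @return Tibble with `sample_id` plus one column per gene set.
#' @method as_tibble functional_spectra
#' @export
as_tibble.functional_spectra <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = rownames(x)),
                   as_tibble(unclass(x), .name_repair = "minimal"))
}
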