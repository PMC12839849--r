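
#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene ids as row
#' names and unique sample ids as column names, holding finite log-scale
#' values. This validator is applied by every reader and simulator before a
#' matrix enters the pipeline.
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly classed as `expr_matrix`.
#' @export
as_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("Expression data must be a numeric matrix (genes x samples).")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    abort("Expression matrix needs at least 2 genes and 2 samples.")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("Expression matrix must carry gene row names and sample column names.")
  }
  stop_if_duplicated(rownames(x), "gene")
  stop_if_duplicated(colnames(x), "sample")
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    abort(glue(
      "Non-finite expression value at gene '{rownames(x)[bad[1L]]}', ",
      "sample '{colnames(x)[bad[2L]]}'; missing values are not imputed."
    ))
  }
  class(x) <- unique(c("expr_matrix", class(x)))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column
#' (genes-in-rows, the GEO series-matrix convention). Orientation is never
#' inferred; pass `transpose = TRUE` for samples-in-rows files.
#'
#' @param path Path to a tab-separated file.
#' @param transpose If `TRUE` the file is samples x genes and is transposed
#'   after reading.
#' @param collapse_map Optional data frame with columns `probe` and `gene`.
#'   When given, probe-level rows are collapsed to genes by keeping, per gene,
#'   the probe with the maximum average expression.
#' @return A validated genes x samples `expr_matrix`.
#' @export
read_expression <- function(path, transpose = FALSE, collapse_map = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2L) abort("Expression TSV needs an id column plus >=1 sample.")
  ids <- df[[1L]]
  stop_if_duplicated(ids, if (transpose) "sample" else "gene")
  raw <- as.matrix(df[-1L])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    abort(glue(
      "Non-numeric expression cell at row '{ids[bad[1L, 1L]]}', ",
      "column '{colnames(df)[-1L][bad[1L, 2L]]}'."
    ))
  }
  mat <- num
  rownames(mat) <- ids
  colnames(mat) <- colnames(df)[-1L]
  if (transpose) mat <- t(mat)
  if (!is.null(collapse_map)) mat <- collapse_probes(mat, collapse_map)
  as_expression_matrix(mat)
}

# keep, per gene symbol, the probe row with maximum average expression
collapse_probes <- function(mat, collapse_map) {
  stopifnot(all(c("probe", "gene") %in% names(collapse_map)))
  map <- collapse_map[collapse_map$probe %in% rownames(mat), , drop = FALSE]
  if (nrow(map) == 0L) abort("No probes of the collapse map are present.")
  avg <- rowMeans(mat)[map$probe]
  keep <- map |>
    dplyr::mutate(avg = avg) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$avg, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- mat[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  out
}

#' Write an expression matrix to TSV
#'
#' @param x Genes x samples matrix.
#' @param path Output path; first column `gene_id`, then one column per sample.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  df <- dplyr::bind_cols(
    tibble(gene_id = rownames(x)),
    as_tibble(unclass(x), .name_repair = "minimal")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
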