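
#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene ids. Members are
#'   deduplicated; empty sets (after dedup) are rejected.
#' @param descriptions Optional character vector, one free-text description
#'   per set (recycled `""` when missing).
#' @return A `gene_sets` object (named list with a `descriptions` attribute).
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of gene id vectors.")
  }
  stop_if_duplicated(names(sets), "gene set")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty) > 0L) {
    abort(glue("Empty gene set(s) after deduplication: {paste(empty, collapse = ', ')}."))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  structure(sets, descriptions = setNames(descriptions, names(sets)),
            class = "gene_sets")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' member gene ids. Members are deduplicated per set; sets whose unique size
#' falls outside `[min_size, max_size]` are dropped with a message.
#'
#' @param path Path to a GMT file. An empty file yields an empty collection.
#' @param min_size,max_size Inclusive bounds on unique set size.
#' @return A `gene_sets` collection; the number of size-filtered sets is
#'   stored in attribute `n_dropped`.
#' @export
read_gmt <- function(path, min_size = 1L, max_size = Inf) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- structure(list(), descriptions = character(), class = "gene_sets")
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(glue("Malformed GMT line {short[1L]}: fewer than 3 tab-separated fields."))
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  stop_if_duplicated(nm, "gene set")
  desc <- vapply(fields, `[[`, character(1L), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(glue("Dropped {n_dropped} gene set(s) outside size [{min_size}, {max_size}]."))
  }
  out <- gene_sets(setNames(members[keep], nm[keep]), desc[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_sets` collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(glue("<gene_sets> {length(x)} set(s)"), "\n")
  if (length(x) > 0L) {
    sz <- lengths(x)
    cat(glue("  sizes: min {min(sz)}, median {median(sz)}, max {max(sz)}"), "\n")
  }
  invisible(x)
}
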