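
# shared input checks ---------------------------------------------------------

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(glue("`{name}` must be a single finite number."))
  }
  if (x < min || x > max) {
    abort(glue("`{name}` must be in [{min}, {max}], got {x}."))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, min = min)
  if (x != as.integer(x)) abort(glue("`{name}` must be a whole number."))
  invisible(as.integer(x))
}

#' @noRd
stop_if_duplicated <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(glue(
      "Duplicate {what} id(s): {paste(head(dup, 5L), collapse = ', ')}."
    ))
  }
  invisible(ids)
}

# FNV-1a style 32-bit hash over a character scalar; provenance only.
# Doubles stay below 2^53: the byte xor touches only the low 8 bits and the
# 32-bit modular multiply is split into 16-bit halves.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# draw one sub-seed per named component from a master seed, so that adding a
# downstream simulation stage never perturbs the draws of an earlier stage
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

component_seeds <- function(seed, components) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(components)), components)
}

with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  force(code)
}
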