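
BUNDLE_FORMAT_VERSION <- "1.0"

#' Create a model bundle
#'
#' A bundle is the serialized form of any fitted pipeline stage: a stage
#' name, a flat named list of parameters (numeric arrays, scalars, character
#' vectors), and provenance metadata. Numeric arrays are stored as
#' base64-encoded IEEE doubles so round-trips are lossless while the file
#' stays human-inspectable JSON.
#'
#' @param stage Name of the pipeline stage (e.g. `"subtype_classifier"`).
#' @param parameters Named list of numeric arrays/scalars, integer, logical
#'   or character elements.
#' @param seed Optional seed recorded in provenance.
#' @return A `model_bundle` object.
#' @export
model_bundle <- function(stage, parameters = list(), seed = NULL) {
  stopifnot(is.character(stage), length(stage) == 1L)
  if (length(parameters) > 0L &&
      (is.null(names(parameters)) || any(names(parameters) == ""))) {
    abort("`parameters` must be a fully named list.")
  }
  structure(
    list(
      stage = stage,
      parameters = parameters,
      provenance = list(
        seed = seed,
        config_hash = fnv1a_hash(paste(
          stage, paste(names(parameters), collapse = ","), collapse = "|"
        )),
        created = format(Sys.time(), tz = "UTC", usetz = TRUE)
      )
    ),
    class = "model_bundle"
  )
}

encode_param <- function(x) {
  if (is.double(x)) {
    list(kind = "double", dim = if (is.null(dim(x))) length(x) else dim(x),
         dimnames = dimnames(x), names = names(x),
         data = jsonlite::base64_enc(writeBin(as.vector(x), raw(), size = 8L)))
  } else if (is.integer(x)) {
    list(kind = "integer", dim = if (is.null(dim(x))) length(x) else dim(x),
         dimnames = dimnames(x), names = names(x), data = as.vector(x))
  } else if (is.character(x) || is.logical(x)) {
    list(kind = typeof(x), data = x, names = names(x))
  } else {
    abort(glue("Unsupported parameter type '{typeof(x)}' in bundle."))
  }
}

decode_param <- function(p) {
  out <- switch(p$kind,
    double = readBin(jsonlite::base64_dec(p$data), what = "double",
                     n = prod(unlist(p$dim)), size = 8L),
    integer = as.integer(unlist(p$data)),
    character = as.character(unlist(p$data)),
    logical = as.logical(unlist(p$data)),
    abort(glue("Unknown parameter kind '{p$kind}' in bundle."))
  )
  if (p$kind %in% c("double", "integer")) {
    d <- unlist(p$dim)
    if (length(d) > 1L) {
      dim(out) <- d
      if (!is.null(p$dimnames)) dimnames(out) <- lapply(p$dimnames, unlist)
    }
  }
  if (!is.null(p$names) && is.null(dim(out))) names(out) <- unlist(p$names)
  out
}

#' Save / load a model bundle as JSON
#'
#' `load_bundle(save_bundle(b, path))` reproduces integer and character
#' parameters bit-identically and doubles exactly (binary encoding). A file
#' written by a different format version, or a truncated/tampered file, is a
#' hard error rather than silent corruption.
#'
#' @param bundle A `model_bundle`.
#' @param path JSON path.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` the bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  payload <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    stage = bundle$stage,
    provenance = bundle$provenance,
    parameters = lapply(bundle$parameters, encode_param)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(glue("Cannot parse bundle '{path}': {conditionMessage(e)}"))
  )
  ver <- payload$format_version
  if (is.null(ver) || !identical(ver, BUNDLE_FORMAT_VERSION)) {
    abort(glue(
      "Bundle format version mismatch: expected {BUNDLE_FORMAT_VERSION}, ",
      "found {ver %||% '<missing>'}."
    ))
  }
  if (is.null(payload$stage) || is.null(payload$parameters)) {
    abort(glue("Bundle '{path}' is incomplete (missing stage or parameters)."))
  }
  structure(
    list(
      stage = payload$stage,
      parameters = lapply(payload$parameters, decode_param),
      provenance = payload$provenance
    ),
    class = "model_bundle"
  )
}
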