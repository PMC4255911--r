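#' Normalize a compact identifier (CURIE)
#'
#' Concept identifiers have the form `"PREFIX:LOCALID"` (e.g. `"FMA:83066"`).
#' Source vocabularies print them inconsistently — `"NCI: C25378"` and
#' `"MESH:D010313"` are both in circulation — so normalization removes
#' whitespace around the first `":"` and trims the ends. Case is preserved:
#' matching elsewhere in the package treats the prefix case-insensitively
#' (`"FMA"` equals `"fma"`) and the local id case-sensitively.
#'
#' @param x character vector of raw curies.
#' @return character vector of normalized curies.
#' @examples
#' normalize_curie("NCI: C25378")  # "NCI:C25378"
#' @export
normalize_curie <- function(x) {
  stopifnot(is.character(x))
  x <- trimws(x)
  x <- sub("[ \t]*:[ \t]*", ":", x)
  bad <- !grepl("^[^:[:space:]]+:[^[:space:]]+$", x) |
    !grepl(":", x, fixed = TRUE)
  if (any(bad)) {
    stop("invalid curie (need non-empty PREFIX:LOCALID): ",
         paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname normalize_curie
#' @return `curie_key()` returns the canonical matching key: the prefix
#'   upper-cased, the local id untouched.
#' @export
curie_key <- function(x) {
  i <- regexpr(":", x, fixed = TRUE)
  paste0(toupper(substr(x, 1L, i - 1L)), substr(x, i, nchar(x)))
}

curie_prefix <- function(x) {
  sub(":.*$", "", x)
}
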