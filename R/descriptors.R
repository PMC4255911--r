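#' Combinatorial semantic descriptors
#'
#' A semantic descriptor annotates one parameter (a model variable, a
#' clinical measurement) with a *set* of ontology concepts that together
#' carry its full meaning — e.g. a pressure concept, a substance concept
#' and an anatomical compartment. Concepts should come from a single
#' ontology where possible, and from several orthogonal ontologies when no
#' single one suffices. Descriptors may optionally carry internal edges
#' between their elements; the similarity machinery scores those too.
#'
#' @param id parameter identifier (free text).
#' @param elements data.frame with columns `curie` and `label`, or a
#'   character vector of curies (labels then empty). Order is preserved
#'   but carries no meaning for scoring. Duplicate curies are rejected.
#' @param edges optional data.frame with columns `from`, `to`, `class`;
#'   both endpoints must be descriptor elements.
#' @return an object of class `semantic_descriptor`.
#' @seealso [parse_descriptor()] for the text dialect,
#'   [match_descriptors()] for scoring.
#' @export
semantic_descriptor <- function(id, elements, edges = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.character(elements)) {
    elements <- data.frame(curie = elements,
                           label = rep("", length(elements)))
  }
  elements <- as.data.frame(elements, stringsAsFactors = FALSE)
  if (!nrow(elements)) {
    stop("descriptor ", sQuote(id), " has no elements", call. = FALSE)
  }
  elements$curie <- normalize_curie(elements$curie)
  if (is.null(elements$label)) elements$label <- ""
  key <- curie_key(elements$curie)
  if (anyDuplicated(key)) {
    stop("duplicate curie in descriptor ", sQuote(id), ": ",
         sQuote(elements$curie[duplicated(key)][1]), call. = FALSE)
  }
  if (is.null(edges) || !NROW(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        class = character())
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("from", "to", "class")
    edges$from <- normalize_curie(edges$from)
    edges$to <- normalize_curie(edges$to)
    bad <- !(curie_key(edges$from) %in% key) | !(curie_key(edges$to) %in% key)
    if (any(bad)) {
      stop("descriptor ", sQuote(id), ": edge endpoint not an element: ",
           sQuote(c(edges$from, edges$to)[c(bad, bad)][1]), call. = FALSE)
    }
  }
  rownames(elements) <- NULL
  structure(list(id = id, elements = elements[, c("curie", "label")],
                 edges = edges),
            class = "semantic_descriptor")
}

#' @export
print.semantic_descriptor <- function(x, ...) {
  cat("<semantic_descriptor>", x$id, "—", nrow(x$elements), "elements",
      if (nrow(x$edges)) paste0(", ", nrow(x$edges), " edges"), "\n")
  cat(" ", render_descriptor(x), "\n")
  invisible(x)
}

#' Parse / render the semicolon descriptor dialect
#'
#' The text form lists concepts separated by `";"`, each as a curie
#' followed by its free-text label, e.g.
#' `"MESH:D010313 Partial Pressure; PubChem:977 Oxygen"`. The curie is the
#' first whitespace token containing `":"`; whitespace after the colon is
#' tolerated (`"NCI: C25378"` parses as `NCI:C25378`).
#'
#' @param text descriptor string.
#' @param id parameter identifier to attach.
#' @return `parse_descriptor()` returns a [semantic_descriptor()];
#'   `render_descriptor()` returns the text form (internal edges are not
#'   rendered — use the JSON form for descriptors with edges).
#' @examples
#' d <- parse_descriptor(
#'   "MESH:D010313 Partial Pressure; PubChem:977 Oxygen", "PaO2")
#' d$elements$curie
#' @export
parse_descriptor <- function(text, id = "query") {
  stopifnot(is.character(text), length(text) == 1L)
  frags <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  frags <- frags[nzchar(frags)]
  if (!length(frags)) {
    stop("empty descriptor text for ", sQuote(id), call. = FALSE)
  }
  parsed <- lapply(frags, function(f) {
    toks <- strsplit(f, "[ \t]+")[[1]]
    ci <- which(grepl(":", toks, fixed = TRUE))
    if (!length(ci)) {
      stop("descriptor fragment without a curie: ", sQuote(f), call. = FALSE)
    }
    ci <- ci[[1]]
    curie <- toks[[ci]]
    rest <- toks[-ci]
    if (grepl(":$", curie)) {
      # "NCI: C25378" split across tokens
      if (ci == length(toks)) {
        stop("descriptor fragment with dangling ':' : ", sQuote(f),
             call. = FALSE)
      }
      curie <- paste0(curie, toks[[ci + 1L]])
      rest <- toks[-c(ci, ci + 1L)]
    }
    c(normalize_curie(curie), paste(rest, collapse = " "))
  })
  semantic_descriptor(id, data.frame(
    curie = vapply(parsed, `[[`, "", 1L),
    label = vapply(parsed, `[[`, "", 2L)))
}

#' @rdname parse_descriptor
#' @param descriptor a `semantic_descriptor`.
#' @export
render_descriptor <- function(descriptor) {
  stopifnot(inherits(descriptor, "semantic_descriptor"))
  paste(trimws(paste(descriptor$elements$curie, descriptor$elements$label)),
        collapse = "; ")
}

#' Read a batch of descriptors from a TSV file
#'
#' Two tab-separated columns: `parameter_id`, `descriptor_text` (the
#' semicolon dialect of [parse_descriptor()]). A header line is detected
#' and skipped when the second field of the first line contains no `":"`.
#'
#' @param path TSV file.
#' @return named list of [semantic_descriptor()] objects.
#' @export
read_descriptor_table <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   comment.char = "#", quote = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) {
    stop("descriptor table ", sQuote(path),
         " needs columns (parameter_id, descriptor_text)", call. = FALSE)
  }
  if (nrow(df) && !grepl(":", df[1, 2], fixed = TRUE)) {
    df <- df[-1, , drop = FALSE]  # header line
  }
  if (!nrow(df)) stop("descriptor table ", sQuote(path), " is empty",
                      call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate parameter_id in ", sQuote(path), ": ",
         sQuote(ids[duplicated(ids)][1]), call. = FALSE)
  }
  out <- Map(parse_descriptor, df[[2]], ids)
  setNames(out, ids)
}

#' JSON form of a descriptor
#'
#' `{id, elements: [{curie, label}], edges: [[from, to, class]]}` — the
#' lossless serialization (the text dialect cannot carry internal edges).
#'
#' @param descriptor a `semantic_descriptor`.
#' @param path file path.
#' @return `read_descriptor_json()` returns a `semantic_descriptor`.
#' @export
write_descriptor_json <- function(descriptor, path) {
  stopifnot(inherits(descriptor, "semantic_descriptor"))
  out <- list(id = descriptor$id, elements = descriptor$elements,
              edges = unname(apply(descriptor$edges, 1L, as.list,
                                   simplify = FALSE)))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  })
  invisible(path)
}

#' @rdname write_descriptor_json
#' @export
read_descriptor_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- NULL
  if (length(x$edges)) {
    edges <- if (is.data.frame(x$edges)) x$edges else
      as.data.frame(matrix(unlist(x$edges), ncol = 3L, byrow = TRUE,
                           dimnames = list(NULL, c("from", "to", "class"))))
  }
  semantic_descriptor(x$id, x$elements, edges)
}
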