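#' Merged multi-ontology concept graphs
#'
#' A `concept_graph` holds concepts (curie, label, source ontology prefix)
#' and typed relations between them. Relations within one ontology
#' (`is_a`, `part_of`, ...) and mappings between ontologies (`xref`,
#' `mapped_to`, ...) are kept in a single undirected graph: both kinds feed
#' ontological inference, in which two concepts count as "similar" when a
#' short chain of relations connects them.
#'
#' @param concepts data.frame with columns `curie`, `label`, `source`
#'   (ontology prefix) and optionally `stub` (logical: concept only ever
#'   seen as a relation endpoint).
#' @param relations data.frame with columns `subject`, `predicate`,
#'   `object`; a `kind` column (`"intra_ontology"`/`"inter_ontology"`) is
#'   recomputed from the prefixes regardless of input.
#' @return an object of class `concept_graph` with elements `concepts`,
#'   `relations` and an internal igraph used for distance queries.
#' @seealso [build_concept_graph()] to assemble one from files,
#'   [concept_distance()] for the step-count metric.
#' @export
concept_graph <- function(concepts = NULL, relations = NULL) {
  if (is.null(concepts)) {
    concepts <- data.frame(curie = character(), label = character(),
                           source = character(), stub = logical())
  }
  if (is.null(relations)) {
    relations <- data.frame(subject = character(), predicate = character(),
                            object = character())
  }
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(concepts)) {
    concepts$curie <- normalize_curie(concepts$curie)
    if (is.null(concepts$label)) concepts$label <- ""
    concepts$label[is.na(concepts$label)] <- ""
    concepts$source <- curie_prefix(concepts$curie)
    if (is.null(concepts$stub)) concepts$stub <- FALSE
  } else {
    concepts <- data.frame(curie = character(), label = character(),
                           source = character(), stub = logical())
  }
  if (nrow(relations)) {
    relations$subject <- normalize_curie(relations$subject)
    relations$object <- normalize_curie(relations$object)
    if (any(!nzchar(relations$predicate))) {
      stop("relation with empty predicate", call. = FALSE)
    }
  } else {
    relations <- data.frame(subject = character(), predicate = character(),
                            object = character())
  }

  # collapse duplicate concepts (first occurrence wins; real beats stub)
  key <- curie_key(concepts$curie)
  if (anyDuplicated(key)) {
    ord <- order(concepts$stub)  # non-stubs first
    concepts <- concepts[ord, , drop = FALSE]
    concepts <- concepts[!duplicated(curie_key(concepts$curie)), , drop = FALSE]
  }

  # stub concepts for dangling relation endpoints
  have <- curie_key(concepts$curie)
  ends <- unique(c(relations$subject, relations$object))
  miss <- ends[!(curie_key(ends) %in% have)]
  miss <- miss[!duplicated(curie_key(miss))]
  if (length(miss)) {
    concepts <- rbind(concepts, data.frame(
      curie = miss, label = "", source = curie_prefix(miss), stub = TRUE))
  }

  # canonical relation triples; duplicates collapsed on matching keys
  if (nrow(relations)) {
    relations$kind <- ifelse(
      toupper(curie_prefix(relations$subject)) ==
        toupper(curie_prefix(relations$object)),
      "intra_ontology", "inter_ontology")
    trip <- paste(curie_key(relations$subject), relations$predicate,
                  curie_key(relations$object), sep = "\r")
    relations <- relations[!duplicated(trip), , drop = FALSE]
  } else {
    relations$kind <- character()
  }
  rownames(concepts) <- NULL
  rownames(relations) <- NULL

  g <- igraph::make_empty_graph(n = nrow(concepts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = curie_key(concepts$curie))
  if (nrow(relations)) {
    g <- igraph::add_edges(
      g, rbind(curie_key(relations$subject), curie_key(relations$object)))
  }
  structure(list(concepts = concepts, relations = relations, graph = g),
            class = "concept_graph")
}

#' @export
print.concept_graph <- function(x, ...) {
  cat("<concept_graph>", nrow(x$concepts), "concepts (",
      sum(x$concepts$stub), "stubs ),", nrow(x$relations), "relations\n")
  src <- table(x$concepts$source)
  cat("  ontologies:", paste0(names(src), " (", src, ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' Parse a subset of the OBO 1.2 flat-file format
#'
#' Reads `[Term]` stanzas and extracts `id`, `name`, `is_a`,
#' `relationship` and `xref` fields; everything else (synonyms, defs,
#' obsolete flags, header) is ignored. Trailing `! comment` text on tag
#' lines is stripped, as is the optional quoted description after an xref.
#'
#' @param lines character vector of OBO lines, or a length-1 path to an
#'   OBO file.
#' @return list with `concepts` and `relations` data.frames as accepted by
#'   [concept_graph()].
#' @export
parse_obo <- function(lines) {
  if (length(lines) == 1L && !grepl("\n", lines) && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  rels <- list()
  flush <- function(cur, ln) {
    if (!is.null(cur) && is.null(cur$id)) {
      stop("malformed OBO stanza: [Term] without id (ends before line ",
           ln, ")", call. = FALSE)
    }
    cur
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      cur <- flush(cur, ln)
      if (!is.null(cur)) terms[[length(terms) + 1L]] <- cur
      in_term <- identical(line, "[Term]")
      cur <- if (in_term) list(id = NULL, name = "") else NULL
      next
    }
    if (!in_term) next
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0) {
      stop("malformed OBO stanza at line ", ln, ": ", sQuote(line),
           call. = FALSE)
    }
    tag <- substr(line, 1L, m - 1L)
    val <- trimws(substr(line, m + 1L, nchar(line)))
    val <- trimws(sub("!.*$", "", val))  # strip trailing comment
    if (tag == "id") {
      cur$id <- normalize_curie(val)
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "is_a") {
      cur$rel <- c(cur$rel, list(c("is_a", normalize_curie(val))))
    } else if (tag == "relationship") {
      parts <- strsplit(val, "[ \t]+")[[1]]
      if (length(parts) < 2L) {
        stop("malformed relationship at line ", ln, ": ", sQuote(line),
             call. = FALSE)
      }
      cur$rel <- c(cur$rel,
                   list(c(parts[[1]], normalize_curie(parts[[2]]))))
    } else if (tag == "xref") {
      val <- trimws(sub("\".*$", "", val))  # drop quoted description
      if (nzchar(val)) {
        cur$rel <- c(cur$rel, list(c("xref", normalize_curie(val))))
      }
    }
  }
  cur <- flush(cur, length(lines))
  if (!is.null(cur)) terms[[length(terms) + 1L]] <- cur

  concepts <- data.frame(
    curie = vapply(terms, `[[`, "", "id"),
    label = vapply(terms, `[[`, "", "name"))
  rel_rows <- do.call(rbind, lapply(terms, function(t) {
    if (is.null(t$rel)) return(NULL)
    do.call(rbind, lapply(t$rel, function(r) {
      data.frame(subject = t$id, predicate = r[[1]], object = r[[2]])
    }))
  }))
  if (is.null(rel_rows)) {
    rel_rows <- data.frame(subject = character(), predicate = character(),
                           object = character())
  }
  list(concepts = concepts, relations = rel_rows)
}

#' Read a 3-column relation or mapping table
#'
#' UTF-8 TSV with columns (subject, predicate, object); lines starting
#' with `#` are comments. Used both for intra-ontology relation extracts
#' and for inter-ontology mapping tables (e.g. UMLS-derived
#' vocabulary crosswalks).
#'
#' @param path TSV file path.
#' @return data.frame with columns `subject`, `predicate`, `object`.
#' @export
read_relation_table <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   colClasses = "character", blank.lines.skip = TRUE,
                   quote = "", fileEncoding = "UTF-8")
  if (nrow(df) && ncol(df) != 3L) {
    stop("relation table ", sQuote(path), " must have exactly 3 columns, found ",
         ncol(df), call. = FALSE)
  }
  if (!nrow(df)) {
    return(data.frame(subject = character(), predicate = character(),
                      object = character()))
  }
  names(df) <- c("subject", "predicate", "object")
  empty <- !nzchar(trimws(df$subject)) | !nzchar(trimws(df$object))
  if (any(empty)) {
    stop("relation table ", sQuote(path), ": empty curie in row ",
         which(empty)[1], call. = FALSE)
  }
  df
}

#' Build a merged concept graph from ontology sources
#'
#' Takes any mix of OBO flat files, intra-ontology relation tables and
#' inter-ontology mapping tables and merges them into one
#' [concept_graph()]. Concepts referenced only as relation endpoints are
#' created as stub concepts (empty label, `stub = TRUE`) so that partial
#' ontology extracts remain usable. Duplicate relation triples are
#' collapsed.
#'
#' @param obo_sources character vector of OBO file paths (or a list of
#'   line vectors).
#' @param relation_tables character vector of 3-column TSV paths.
#' @param mapping_tables character vector of 3-column TSV paths; kept
#'   separate from `relation_tables` purely for provenance — both end up
#'   as relations, with `kind` derived from the curie prefixes.
#' @return a `concept_graph`.
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root",
#'          "[Term]", "id: T:2", "name: child", "is_a: T:1")
#' g <- build_concept_graph(obo_sources = list(obo))
#' concept_distance(g, "T:2", "T:1")  # 1
#' @export
build_concept_graph <- function(obo_sources = list(),
                                relation_tables = character(),
                                mapping_tables = character()) {
  if (is.character(obo_sources)) obo_sources <- as.list(obo_sources)
  parsed <- lapply(obo_sources, parse_obo)
  concepts <- do.call(rbind, c(
    list(data.frame(curie = character(), label = character())),
    lapply(parsed, `[[`, "concepts")))
  relations <- do.call(rbind, c(
    list(data.frame(subject = character(), predicate = character(),
                    object = character())),
    lapply(parsed, `[[`, "relations"),
    lapply(as.character(relation_tables), read_relation_table),
    lapply(as.character(mapping_tables), read_relation_table)))
  concept_graph(concepts, relations)
}

#' Step-count distance between two concepts
#'
#' The inference primitive: the minimum number of relation traversals
#' between two concepts, treating every relation as bidirectional and
#' every relation class (`is_a`, `part_of`, `xref`, `mapped_to`, ...) as
#' one step. Similarity scoring divides 1 by a function of this count, so
#' concepts beyond `max_steps` contribute nothing and the search is cut
#' off there. The default `max_steps = 3` keeps inference local: beyond 3
#' hops an element score falls to 0.25 or less.
#'
#' @param graph a [concept_graph()].
#' @param a,b curies (prefix matched case-insensitively).
#' @param max_steps maximum path length to consider (default 3).
#' @return integer step count, or `NA` if no path of length `<= max_steps`
#'   exists. `0` iff `a` and `b` are the same concept.
#' @export
concept_distance <- function(graph, a, b, max_steps = 3L) {
  stopifnot(inherits(graph, "concept_graph"))
  if (!is.numeric(max_steps) || length(max_steps) != 1L || max_steps < 0) {
    stop("max_steps must be a non-negative integer", call. = FALSE)
  }
  ka <- curie_key(normalize_curie(a))
  kb <- curie_key(normalize_curie(b))
  have <- igraph::V(graph$graph)$name
  for (k in c(ka, kb)) {
    if (!(k %in% have)) {
      stop("unknown curie: ", sQuote(k), call. = FALSE)
    }
  }
  if (ka == kb) return(0L)
  d <- igraph::distances(graph$graph, v = ka, to = kb)[1, 1]
  if (!is.finite(d) || d > max_steps) NA_integer_ else as.integer(d)
}

# distance matrix between two sets of curie keys; Inf where unreachable
# or either key is absent from the graph (isolated stub semantics)
concept_distance_matrix <- function(graph, from_keys, to_keys, max_steps) {
  have <- igraph::V(graph$graph)$name
  d <- matrix(Inf, length(from_keys), length(to_keys),
              dimnames = list(from_keys, to_keys))
  fi <- from_keys %in% have
  ti <- to_keys %in% have
  if (any(fi) && any(ti)) {
    d[fi, ti] <- igraph::distances(graph$graph, v = from_keys[fi],
                                   to = to_keys[ti])
  }
  d[outer(from_keys, to_keys, "==")] <- 0
  d[d > max_steps] <- Inf
  d
}

#' Serialize a concept graph to JSON / read it back
#'
#' Round-trips a graph between CLI invocations as a single JSON document
#' `{"concepts": [...], "relations": [...]}`.
#'
#' @param graph a `concept_graph`.
#' @param path output (or input) file path.
#' @return `read_concept_graph()` returns a `concept_graph`;
#'   `write_concept_graph()` returns `path` invisibly.
#' @export
write_concept_graph <- function(graph, path) {
  stopifnot(inherits(graph, "concept_graph"))
  out <- list(concepts = graph$concepts,
              relations = graph$relations[, c("subject", "predicate",
                                              "object", "kind")])
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = FALSE)
  })
  invisible(path)
}

#' @rdname write_concept_graph
#' @export
read_concept_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  concept_graph(x$concepts, x$relations)
}
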