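#' Element score as a function of inference steps
#'
#' An identical concept match scores exactly 1. A concept reached through
#' `k >= 1` relation steps (ontological inference) scores with diminishing
#' contribution in `k`. Two variants are provided:
#'
#' * `"damped"` (default): `s(0) = 1`, `s(k) = 1/(1+k)` — strictly
#'   decreasing from step 0 onward, so a 1-step neighbour (0.5) is always
#'   distinguishable from an identical match (1).
#' * `"literal"`: `s(0) = 1`, `s(k) = 1/k` — the plain reciprocal of the
#'   step count. Note `s(1) = 1` ties with an identical match; the variant
#'   is kept for comparability only.
#'
#' @param steps non-negative integer vector of step counts.
#' @param score_fn `"damped"` or `"literal"`.
#' @return numeric vector of scores in `(0, 1]`.
#' @examples
#' element_score(0:3)            # 1, 0.5, 1/3, 0.25
#' element_score(1, "literal")   # 1
#' @export
element_score <- function(steps, score_fn = c("damped", "literal")) {
  score_fn <- match.arg(score_fn)
  if (!is.numeric(steps) || any(is.na(steps)) || any(steps < 0)) {
    stop("steps must be non-negative", call. = FALSE)
  }
  switch(score_fn,
         damped = ifelse(steps == 0, 1, 1 / (1 + steps)),
         literal = ifelse(steps == 0, 1, 1 / steps))
}

# ---- optimal one-to-one assignment ------------------------------------
#
# Maximize the total element score over injective partial assignments of
# query elements to target elements. Descriptors are small (a handful of
# concepts), so an exact depth-first search with an upper-bound prune is
# both fast and verifiable against brute force. Among equal-score optima
# the assignment chosen is lexicographically smallest in (query curie,
# target curie): rows are processed in query-curie order and candidate
# targets tried in target-curie order, unmatched last.
assign_elements <- function(S, qnames, tnames) {
  nq <- nrow(S)
  nt <- ncol(S)
  qo <- order(qnames)
  to <- order(tnames)
  S <- S[qo, to, drop = FALSE]
  row_max <- apply(S, 1L, max)
  best_val <- -1
  best_asn <- NULL
  asn <- integer(nq)  # 0 = unmatched, else column index
  used <- logical(nt)
  eps <- 1e-12
  rec <- function(i, acc) {
    if (i > nq) {
      if (acc > best_val + eps) {
        best_val <<- acc
        best_asn <<- asn
      }
      return(invisible())
    }
    ub <- acc + sum(row_max[i:nq])
    if (ub < best_val - eps) return(invisible())
    cands <- which(!used & S[i, ] > 0)
    for (j in cands) {          # already in target-curie order
      asn[i] <<- j
      used[j] <<- TRUE
      rec(i + 1L, acc + S[i, j])
      used[j] <<- FALSE
    }
    asn[i] <<- 0L
    rec(i + 1L, acc)
  }
  rec(1L, 0)
  # map back to original row/column indices
  out <- integer(nq)
  out[qo] <- ifelse(best_asn == 0L, 0L, to[pmax(best_asn, 1L)])
  out
}

#' Score the similarity of two semantic descriptors
#'
#' Implements the network-similarity rule for combinatorial descriptors.
#' Every query element is compared with every target element through the
#' concept graph: identical concepts match at 0 steps (score 1), concepts
#' connected by at most `max_steps` intra-/inter-ontology relations match
#' "similarly" with score [element_score()] of the step count, and the
#' one-to-one assignment of query to target elements maximizing the score
#' sum is selected exactly. Query edges are scored after elements:
#' an identical edge (both endpoints identically matched, same class)
#' scores 1; a similar edge scores `1/(1 + steps(a) + steps(b) + m)` with
#' `m = 1` when the edge class differs; anything else is unmatched (0).
#'
#' Aggregates follow the rule *total = sum of individual scores x
#' coverage*, with coverage the fraction of query elements and edges
#' recovered (identically or similarly) in the target, and
#' `normalized = total / (query elements + query edges)` so that
#' self-similarity is exactly 1. Scores are computed over the *query's*
#' elements: when the two descriptors differ in size the two directions
#' may differ.
#'
#' @param query,target [semantic_descriptor()] objects.
#' @param graph a [concept_graph()]; curies absent from it are treated as
#'   isolated concepts matching only themselves.
#' @param max_steps inference horizon, see [concept_distance()].
#' @param score_fn see [element_score()].
#' @return object of class `descriptor_similarity`: list with `query_id`,
#'   `target_id`, `element_matches` (data.frame: `query_element`,
#'   `target_element`, `steps`, `score`, `matched_via`), `edge_matches`,
#'   `sum_scores`, `coverage`, `total`, `normalized`.
#' @examples
#' g <- build_concept_graph(obo_sources = list(c(
#'   "[Term]", "id: T:1", "[Term]", "id: T:2", "is_a: T:1")))
#' q <- semantic_descriptor("q", c("T:1", "T:2"))
#' t <- semantic_descriptor("t", c("T:1"))
#' match_descriptors(q, t, g)$normalized
#' @export
match_descriptors <- function(query, target, graph,
                              max_steps = 3L,
                              score_fn = c("damped", "literal")) {
  score_fn <- match.arg(score_fn)
  stopifnot(inherits(query, "semantic_descriptor"),
            inherits(target, "semantic_descriptor"),
            inherits(graph, "concept_graph"))
  if (!nrow(query$elements)) stop("empty query descriptor", call. = FALSE)
  qcur <- query$elements$curie
  tcur <- target$elements$curie
  qk <- curie_key(qcur)
  tk <- curie_key(tcur)

  D <- concept_distance_matrix(graph, qk, tk, max_steps)
  S <- matrix(0, length(qk), length(tk))
  S[is.finite(D)] <- element_score(D[is.finite(D)], score_fn)

  asn <- assign_elements(S, qk, tk)

  steps <- ifelse(asn > 0L, D[cbind(seq_along(asn), pmax(asn, 1L))], NA)
  escore <- ifelse(asn > 0L, S[cbind(seq_along(asn), pmax(asn, 1L))], 0)
  element_matches <- data.frame(
    query_element = qcur,
    target_element = ifelse(asn > 0L, tcur[pmax(asn, 1L)], NA_character_),
    steps = as.integer(steps),
    score = escore,
    matched_via = ifelse(asn == 0L, "unmatched",
                         ifelse(steps == 0, "identical", "similar")))

  # edges: compare query edges against target edges through the element
  # assignment (undirected endpoint comparison)
  edge_matches <- score_edges(query, target, element_matches, tk)

  n_query <- nrow(query$elements) + nrow(query$edges)
  n_matched <- sum(element_matches$matched_via != "unmatched") +
    sum(edge_matches$matched_via != "unmatched")
  sum_scores <- sum(element_matches$score) + sum(edge_matches$score)
  coverage <- n_matched / n_query
  total <- sum_scores * coverage
  structure(list(query_id = query$id, target_id = target$id,
                 element_matches = element_matches,
                 edge_matches = edge_matches,
                 sum_scores = sum_scores, coverage = coverage,
                 total = total, normalized = total / n_query),
            class = "descriptor_similarity")
}

score_edges <- function(query, target, element_matches, tk) {
  empty <- data.frame(query_from = character(), query_to = character(),
                      query_class = character(),
                      target_from = character(), target_to = character(),
                      target_class = character(),
                      score = numeric(), matched_via = character())
  if (!nrow(query$edges)) return(empty)
  qek <- curie_key(element_matches$query_element)
  mapped <- setNames(element_matches$target_element, qek)
  steps <- setNames(element_matches$steps, qek)
  t_edges <- target$edges
  t_from <- curie_key(t_edges$from)
  t_to <- curie_key(t_edges$to)
  rows <- lapply(seq_len(nrow(query$edges)), function(i) {
    e <- query$edges[i, ]
    a <- curie_key(e$from); b <- curie_key(e$to)
    ta <- mapped[[a]]; tb <- mapped[[b]]
    out <- data.frame(query_from = e$from, query_to = e$to,
                      query_class = e$class,
                      target_from = NA_character_, target_to = NA_character_,
                      target_class = NA_character_,
                      score = 0, matched_via = "unmatched")
    if (is.na(ta) || is.na(tb) || !nrow(t_edges)) return(out)
    ka <- curie_key(ta); kb <- curie_key(tb)
    hit <- which((t_from == ka & t_to == kb) | (t_from == kb & t_to == ka))
    if (!length(hit)) return(out)
    # prefer a same-class target edge when one exists
    same <- hit[t_edges$class[hit] == e$class]
    j <- if (length(same)) same[[1]] else hit[[1]]
    mism <- as.integer(t_edges$class[[j]] != e$class)
    k <- steps[[a]] + steps[[b]] + mism
    out$target_from <- t_edges$from[[j]]
    out$target_to <- t_edges$to[[j]]
    out$target_class <- t_edges$class[[j]]
    out$score <- if (k == 0) 1 else 1 / (1 + k)
    out$matched_via <- if (k == 0) "identical" else "similar"
    out
  })
  do.call(rbind, rows)
}

#' @export
print.descriptor_similarity <- function(x, ...) {
  cat(sprintf("<descriptor_similarity> %s vs %s\n", x$query_id, x$target_id))
  cat(sprintf("  sum = %.4g  coverage = %.4g  total = %.4g  normalized = %.4g\n",
              x$sum_scores, x$coverage, x$total, x$normalized))
  print(x$element_matches)
  invisible(x)
}

#' Rank candidate descriptors against a query
#'
#' Scores the query against each target with [match_descriptors()] and
#' orders the results by normalized similarity (descending; ties broken
#' by target id ascending) — e.g. ranking clinical parameters against a
#' model parameter's descriptor.
#'
#' @inheritParams match_descriptors
#' @param targets list of [semantic_descriptor()] objects.
#' @param top_n optional truncation of the ranked list.
#' @return list of `descriptor_similarity` objects, best first.
#' @export
rank_candidates <- function(query, targets, graph, max_steps = 3L,
                            top_n = NULL,
                            score_fn = c("damped", "literal")) {
  score_fn <- match.arg(score_fn)
  if (!length(targets)) stop("no target descriptors", call. = FALSE)
  if (!is.null(top_n) && (!is.numeric(top_n) || top_n <= 0)) {
    stop("top_n must be a positive integer", call. = FALSE)
  }
  res <- lapply(targets, match_descriptors, query = query, graph = graph,
                max_steps = max_steps, score_fn = score_fn)
  ids <- vapply(res, `[[`, "", "target_id")
  norm <- vapply(res, `[[`, 0, "normalized")
  res <- res[order(-norm, ids)]
  if (!is.null(top_n)) res <- head(res, top_n)
  res
}

#' Flatten ranked similarities to a table
#'
#' @param results list of `descriptor_similarity` (e.g. from
#'   [rank_candidates()]).
#' @param detail include per-element match detail as a JSON column.
#' @return data.frame with one row per query/target pair.
#' @export
similarity_table <- function(results, detail = TRUE) {
  if (inherits(results, "descriptor_similarity")) results <- list(results)
  df <- data.frame(
    query_id = vapply(results, `[[`, "", "query_id"),
    target_id = vapply(results, `[[`, "", "target_id"),
    sum_scores = vapply(results, `[[`, 0, "sum_scores"),
    coverage = vapply(results, `[[`, 0, "coverage"),
    total = vapply(results, `[[`, 0, "total"),
    normalized = vapply(results, `[[`, 0, "normalized"))
  if (detail) {
    df$matches <- vapply(results, function(r) {
      as.character(jsonlite::toJSON(r$element_matches, dataframe = "rows",
                                    auto_unbox = TRUE, digits = NA,
                                    na = "null"))
    }, "")
  }
  df
}
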