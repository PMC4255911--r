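#' Typed association networks and penalty tables
#'
#' A `typed_network` is an undirected knowledge graph whose nodes carry a
#' type (gene, disease, metabolite, ...) and whose edges carry an
#' association class (e.g. a co-immunoprecipitation PPI versus a
#' two-hybrid PPI). A `penalty_table` assigns each class a non-negative
#' penalty reflecting its reliability — for instance co-IP = 1,
#' two-hybrid = 3 — so that accumulated path penalty prefers shorter and
#' higher-quality routes. Parallel edges of different classes between the
#' same node pair are retained and searched separately.
#'
#' @param nodes data.frame with columns `id`, `type`, or a character
#'   vector of ids (type then `"node"`).
#' @param edges data.frame with columns `from`, `to`, `class`. Stored
#'   canonically with `from <= to`; exact duplicate triples collapse.
#' @return object of class `typed_network`.
#' @export
typed_network <- function(nodes, edges) {
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes, type = "node")
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$type)) nodes$type <- "node"
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    names(edges)[1:3] <- c("from", "to", "class")
    miss <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(miss)) {
      nodes <- rbind(nodes[, c("id", "type")],
                     data.frame(id = miss, type = "node"))
    }
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[!duplicated(paste(edges$from, edges$to, edges$class,
                                     sep = "\r")), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to, edges$class), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        class = character())
  }
  nodes <- nodes[!duplicated(nodes$id), c("id", "type"), drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  cat("<typed_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      length(unique(x$edges$class)), "classes )\n")
  invisible(x)
}

#' @rdname typed_network
#' @param penalties named numeric vector: edge class -> penalty `>= 0`.
#' @param default_penalty penalty for classes not listed.
#' @export
penalty_table <- function(penalties = numeric(), default_penalty = 1) {
  penalties <- unlist(penalties)
  if (length(penalties) && (is.null(names(penalties)) ||
                            any(!nzchar(names(penalties))))) {
    stop("penalties must be named by edge class", call. = FALSE)
  }
  if (any(penalties < 0) || default_penalty < 0) {
    stop("penalties must be non-negative", call. = FALSE)
  }
  structure(list(penalties = penalties,
                 default_penalty = as.numeric(default_penalty)),
            class = "penalty_table")
}

#' Penalty for a vector of edge classes
#' @param table a [penalty_table()].
#' @param class character vector of edge classes.
#' @return numeric penalties (default for unlisted classes).
#' @export
penalty_for <- function(table, class) {
  stopifnot(inherits(table, "penalty_table"))
  p <- table$penalties[class]
  p[is.na(p)] <- table$default_penalty
  unname(p)
}

#' Load a typed network and its penalty table from TSV files
#'
#' The edge table has columns (node_a, node_b, edge_class) and an
#' optional 4th column with node types as `"typeA|typeB"`. The penalty
#' table has columns (edge_class, penalty). Edge classes with no penalty
#' entry fall back to `default_penalty`, with a warning naming them.
#'
#' @param edge_table path to the edge TSV.
#' @param penalty_file optional path to the penalty TSV.
#' @param default_penalty penalty for unlisted classes.
#' @return list with elements `network` ([typed_network()]) and
#'   `penalties` ([penalty_table()]).
#' @export
load_typed_network <- function(edge_table, penalty_file = NULL,
                               default_penalty = 1) {
  df <- tryCatch(
    read.delim(edge_table, header = FALSE, comment.char = "#",
               colClasses = "character", quote = "",
               fileEncoding = "UTF-8"),
    error = function(e) data.frame())
  if (!nrow(df)) stop("empty edge table: ", sQuote(edge_table), call. = FALSE)
  if (ncol(df) < 3L) {
    stop("edge table ", sQuote(edge_table),
         " needs columns (node_a, node_b, edge_class)", call. = FALSE)
  }
  edges <- data.frame(from = df[[1]], to = df[[2]], class = df[[3]])
  nodes <- data.frame(id = c(df[[1]], df[[2]]), type = "node")
  if (ncol(df) >= 4L) {
    ty <- strsplit(df[[4]], "|", fixed = TRUE)
    ta <- vapply(ty, function(x) x[1] %||% "node", "")
    tb <- vapply(ty, function(x) if (length(x) > 1) x[2] else "node", "")
    nodes$type <- c(ta, tb)
  }
  net <- typed_network(nodes, edges)
  pen <- numeric()
  if (!is.null(penalty_file)) {
    pf <- read.delim(penalty_file, header = FALSE, comment.char = "#",
                     colClasses = "character", quote = "",
                     fileEncoding = "UTF-8")
    if (ncol(pf) < 2L) {
      stop("penalty table ", sQuote(penalty_file),
           " needs columns (edge_class, penalty)", call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(pf[[2]]))
    if (any(is.na(val))) {
      stop("non-numeric penalty for class ",
           sQuote(pf[[1]][is.na(val)][1]), call. = FALSE)
    }
    pen <- setNames(val, pf[[1]])
  }
  tab <- penalty_table(pen, default_penalty)
  unknown <- setdiff(unique(net$edges$class), names(pen))
  if (length(unknown) && length(pen)) {
    warning("edge classes without penalty entry (default ", default_penalty,
            " used): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(network = net, penalties = tab)
}

# adjacency list: for each node, data.frame(to, class, penalty)
adjacency_index <- function(network, penalties) {
  e <- network$edges
  p <- penalty_for(penalties, e$class)
  both <- data.frame(from = c(e$from, e$to), to = c(e$to, e$from),
                     class = c(e$class, e$class), penalty = c(p, p))
  both <- both[order(both$from, both$to, both$class), , drop = FALSE]
  split(both[c("to", "class", "penalty")], factor(both$from,
                                                  levels = network$nodes$id))
}

# lowest accumulated penalty from `source` to every node (uniform-cost
# search, the weighted generalization of breadth-first expansion; exact
# for non-negative penalties)
min_penalty_from <- function(adj, nodes, source) {
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  done <- setNames(logical(length(nodes)), nodes)
  dist[source] <- 0
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    nb <- adj[[names(u)]]
    if (is.null(nb) || !nrow(nb)) next
    alt <- dist[u] + nb$penalty
    upd <- alt < dist[nb$to]
    if (any(upd)) dist[nb$to[upd]] <- alt[upd]
  }
  dist
}

#' Penalty-weighted path search
#'
#' Finds paths between two nodes of a typed network under per-edge-class
#' penalties. The search generalizes breadth-first expansion: instead of
#' hop count, the accumulated penalty along the path is minimized, so
#' with all penalties equal to 1 it reduces exactly to BFS hop distance.
#' Two retention modes:
#'
#' * `mode = "best"`: the complete set of minimum-total-penalty simple
#'   paths, ordered lexicographically by node sequence.
#' * `mode = "all_below"`: all simple paths with total penalty
#'   `<= threshold`, ordered by penalty then node sequence; enumeration
#'   is depth-first with penalty pruning (admissible because penalties
#'   are non-negative) and truncates at `max_paths` with attribute
#'   `truncated = TRUE` — never silently.
#'
#' @param network a [typed_network()].
#' @param penalties a [penalty_table()].
#' @param source,target node ids.
#' @param mode `"best"` or `"all_below"`.
#' @param threshold penalty bound, required for `mode = "all_below"`.
#' @param max_paths cap on the number of returned paths (default 1000).
#' @return list of `path_result` objects (fields `nodes`, `classes`,
#'   `total_penalty`), with attributes `min_penalty` (exact, `Inf` when
#'   disconnected) and `truncated`.
#' @examples
#' net <- typed_network(c("A", "B", "C"),
#'   data.frame(from = c("A", "A", "C"), to = c("B", "C", "B"),
#'              class = c("Y2H", "coIP", "coIP")))
#' pt <- penalty_table(c(coIP = 1, Y2H = 3))
#' penalized_search(net, pt, "A", "B")[[1]]$total_penalty  # 2 via C
#' @export
penalized_search <- function(network, penalties, source, target,
                             mode = c("best", "all_below"),
                             threshold = NULL, max_paths = 1000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "typed_network"),
            inherits(penalties, "penalty_table"))
  nodes <- network$nodes$id
  for (n in c(source, target)) {
    if (!(n %in% nodes)) stop("unknown node: ", sQuote(n), call. = FALSE)
  }
  if (mode == "all_below") {
    if (is.null(threshold)) {
      stop("mode 'all_below' requires a threshold", call. = FALSE)
    }
    if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  }
  if (max_paths < 1L) stop("max_paths must be >= 1", call. = FALSE)

  adj <- adjacency_index(network, penalties)
  h <- min_penalty_from(adj, nodes, target)  # heuristic: exact remainder
  minpen <- unname(h[source])
  eps <- 1e-9
  bound <- if (mode == "best") minpen else threshold
  results <- list()
  truncated <- FALSE

  if (source == target) {
    results[[1]] <- path_result(source, character(), 0)
  } else if (is.finite(bound) && is.finite(minpen) && minpen <= bound + eps) {
    on_path <- logical(length(nodes))
    names(on_path) <- nodes
    walk <- function(u, acc, path, classes) {
      if (truncated) return(invisible())
      if (u == target) {
        if (length(results) >= max_paths) {
          truncated <<- TRUE
          return(invisible())
        }
        results[[length(results) + 1L]] <<- path_result(path, classes, acc)
        return(invisible())
      }
      nb <- adj[[u]]
      if (is.null(nb) || !nrow(nb)) return(invisible())
      for (i in seq_len(nrow(nb))) {
        v <- nb$to[[i]]
        if (on_path[[v]]) next
        acc2 <- acc + nb$penalty[[i]]
        if (acc2 + h[[v]] > bound + eps) next
        on_path[[v]] <<- TRUE
        walk(v, acc2, c(path, v), c(classes, nb$class[[i]]))
        on_path[[v]] <<- FALSE
      }
    }
    on_path[[source]] <- TRUE
    walk(source, 0, source, character())
  }

  if (length(results)) {
    key <- vapply(results, function(p) paste(p$nodes, collapse = "\r"), "")
    pen <- vapply(results, `[[`, 0, "total_penalty")
    ord <- if (mode == "best") order(key) else order(pen, key)
    results <- results[ord]
  }
  attr(results, "min_penalty") <- minpen
  attr(results, "truncated") <- truncated
  results
}

path_result <- function(nodes, classes, total_penalty) {
  structure(list(nodes = nodes, classes = classes,
                 total_penalty = total_penalty),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(paste(x$nodes, collapse = " - "), " (penalty ", x$total_penalty, ")\n",
      sep = "")
  invisible(x)
}

#' Write / read search results as JSON
#'
#' @param results list of `path_result` from [penalized_search()].
#' @param path file path.
#' @return `read_path_results()` returns the list (with `min_penalty` and
#'   `truncated` attributes restored).
#' @export
write_path_results <- function(results, path) {
  out <- list(
    min_penalty = attr(results, "min_penalty") %||% NA,
    truncated = isTRUE(attr(results, "truncated")),
    paths = lapply(results, function(p) {
      list(nodes = p$nodes, classes = p$classes,
           total_penalty = p$total_penalty)
    }))
  if (!is.finite(out$min_penalty)) out$min_penalty <- NULL
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
  })
  invisible(path)
}

#' @rdname write_path_results
#' @export
read_path_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  res <- lapply(x$paths, function(p) {
    path_result(unlist(p$nodes), as.character(unlist(p$classes)),
                p$total_penalty)
  })
  attr(res, "min_penalty") <- x$min_penalty %||% Inf
  attr(res, "truncated") <- isTRUE(x$truncated)
  res
}

#' Rank search-result nodes by quality annotations
#'
#' Takes the nodes appearing on the paths of a search result and assigns
#' each a combined score from external quality values (for example
#' "number of associated diseases" or "variability in muscle
#' expression") and from the best path penalty through the node. Each
#' quality column is min-max normalized over the result nodes, weighted
#' and summed; the normalized best penalty is subtracted with weight
#' `weight_penalty`:
#'
#' `combined = sum_c weights[c] * norm(quality_c) -
#'  weight_penalty * norm(best_penalty)`
#'
#' Nodes missing from the quality table get neutral normalized quality 0;
#' an all-equal column normalizes to 0 for every node (with a warning).
#'
#' @param results list of `path_result` from [penalized_search()].
#' @param quality_table data.frame with column `node_id` (or first
#'   column) plus one numeric column per quality.
#' @param weights named numeric vector over quality columns; columns
#'   without a weight get 0.
#' @param weight_penalty weight of the (normalized) best path penalty
#'   through each node (default 1).
#' @return object of class `node_ranking`: data.frame with `rank`,
#'   `node_id`, `combined_score`, `best_penalty` and one normalized
#'   column per quality; ordered by score descending, id ascending.
#' @export
rank_nodes <- function(results, quality_table = NULL, weights = numeric(),
                       weight_penalty = 1) {
  if (!length(results)) stop("no paths to rank nodes from", call. = FALSE)
  nodes <- sort(unique(unlist(lapply(results, `[[`, "nodes"))))
  best_pen <- vapply(nodes, function(n) {
    min(vapply(results,
               function(p) if (n %in% p$nodes) p$total_penalty else Inf, 0))
  }, 0)

  minmax <- function(x, what, warn = TRUE) {
    rng <- range(x)
    if (!is.finite(diff(rng)) || diff(rng) == 0) {
      if (warn && length(x) > 1L) {
        warning("all-equal values for ", what,
                "; normalized to 0", call. = FALSE)
      }
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng)
  }

  qcols <- list()
  if (!is.null(quality_table) && NROW(quality_table)) {
    quality_table <- as.data.frame(quality_table, stringsAsFactors = FALSE)
    idcol <- if ("node_id" %in% names(quality_table)) "node_id" else
      names(quality_table)[1]
    vals <- quality_table[match(nodes, quality_table[[idcol]]), , drop = FALSE]
    for (col in setdiff(names(quality_table), idcol)) {
      x <- as.numeric(vals[[col]])
      known <- !is.na(x)
      norm <- rep(0, length(nodes))
      if (any(known)) norm[known] <- minmax(x[known], sQuote(col))
      qcols[[col]] <- norm
    }
  }
  w <- setNames(rep(0, length(qcols)), names(qcols))
  w[intersect(names(weights), names(w))] <-
    weights[intersect(names(weights), names(w))]
  qscore <- if (length(qcols)) {
    Reduce(`+`, Map(function(v, wt) v * wt, qcols, w))
  } else rep(0, length(nodes))
  pnorm <- minmax(best_pen, "path penalty", warn = FALSE)
  combined <- qscore - weight_penalty * pnorm

  ord <- order(-combined, nodes)
  out <- data.frame(rank = seq_along(nodes), node_id = nodes[ord],
                    combined_score = combined[ord],
                    best_penalty = best_pen[ord])
  for (col in names(qcols)) out[[paste0("norm_", col)]] <- qcols[[col]][ord]
  rownames(out) <- NULL
  structure(out, class = c("node_ranking", "data.frame"),
            weights = w, weight_penalty = weight_penalty)
}
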