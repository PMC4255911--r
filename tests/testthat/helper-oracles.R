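# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph, except where noted): plain adjacency lists,
# queue-based BFS and unpruned recursive enumeration.

# --- concept-graph oracle ----------------------------------------------

# adjacency list on curie keys from a relations data.frame
oracle_adjacency <- function(relations) {
  s <- kbmine::curie_key(relations$subject)
  o <- kbmine::curie_key(relations$object)
  adj <- list()
  for (i in seq_along(s)) {
    adj[[s[i]]] <- unique(c(adj[[s[i]]], o[i]))
    adj[[o[i]]] <- unique(c(adj[[o[i]]], s[i]))
  }
  adj
}

# plain queue BFS; returns Inf when unreachable
oracle_bfs <- function(adj, a, b) {
  if (a == b) return(0)
  dist <- setNames(0, a)
  queue <- a
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    for (v in adj[[u]]) {
      if (!is.null(dist[v]) && !is.na(dist[v])) next
      dist[v] <- dist[[u]] + 1
      if (v == b) return(unname(dist[v]))
      queue <- c(queue, v)
    }
  }
  Inf
}

# all simple paths between two curie keys (exhaustive recursion), as a
# list of node vectors — used to cross-check BFS distances
oracle_all_paths <- function(adj, a, b, max_len = Inf) {
  out <- list()
  walk <- function(u, path) {
    if (u == b) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= max_len) return(invisible())
    for (v in adj[[u]]) {
      if (v %in% path) next
      walk(v, c(path, v))
    }
  }
  if (a == b) return(list(a))
  walk(a, a)
  out
}

# --- descriptor-matching oracle ----------------------------------------

oracle_score <- function(steps, score_fn = "damped") {
  if (steps == 0) 1
  else if (score_fn == "damped") 1 / (1 + steps)
  else 1 / steps
}

# exhaustive one-to-one assignment: enumerate every injective partial map
# of query elements onto target elements, score with BFS distances, take
# the maximum sum; among optima keep the first in lexicographic
# (query curie, target curie) order with unmatched last.
oracle_match <- function(query, target, graph, max_steps = 3,
                         score_fn = "damped") {
  adj <- oracle_adjacency(graph$relations)
  in_graph <- kbmine::curie_key(graph$concepts$curie)
  qk <- sort(kbmine::curie_key(query$elements$curie))
  tk <- kbmine::curie_key(target$elements$curie)
  tord <- order(tk)
  tk <- tk[tord]
  S <- matrix(0, length(qk), length(tk))
  for (i in seq_along(qk)) {
    for (j in seq_along(tk)) {
      d <- if (qk[i] == tk[j]) 0
      else if (qk[i] %in% in_graph && tk[j] %in% in_graph) {
        oracle_bfs(adj, qk[i], tk[j])
      } else Inf
      if (is.finite(d) && d <= max_steps) {
        S[i, j] <- oracle_score(d, score_fn)
      }
    }
  }
  best <- -1
  best_n_matched <- 0
  # pass 1: maximum achievable sum (full enumeration, no pruning)
  enum <- function(i, used, acc, nm, visit) {
    if (i > length(qk)) {
      visit(acc, nm)
      return(invisible())
    }
    for (j in seq_along(tk)) {
      if (used[j] || S[i, j] <= 0) next
      used[j] <- TRUE
      enum(i + 1L, used, acc + S[i, j], nm + 1L, visit)
      used[j] <- FALSE
    }
    enum(i + 1L, used, acc, nm, visit)
  }
  enum(1L, logical(length(tk)), 0, 0L, function(acc, nm) {
    if (acc > best + 1e-12) {
      best <<- acc
      best_n_matched <<- nm
    }
  })
  # pass 2: first assignment (in lex enumeration order) achieving it
  found <- FALSE
  enum(1L, logical(length(tk)), 0, 0L, function(acc, nm) {
    if (!found && abs(acc - best) <= 1e-9) {
      best_n_matched <<- nm
      found <<- TRUE
    }
  })
  n_query <- nrow(query$elements)
  coverage <- best_n_matched / n_query
  list(sum_scores = best, coverage = coverage, total = best * coverage,
       normalized = best * coverage / n_query)
}

# --- penalized-search oracle -------------------------------------------

# exhaustive enumeration of every simple path and its penalty, straight
# off the edge table (parallel class edges enumerated separately)
oracle_search <- function(network, penalties, source, target) {
  e <- network$edges
  pen <- kbmine::penalty_for(penalties, e$class)
  nb <- list()
  for (i in seq_len(nrow(e))) {
    nb[[e$from[i]]] <- c(nb[[e$from[i]]], list(list(to = e$to[i], p = pen[i])))
    nb[[e$to[i]]] <- c(nb[[e$to[i]]], list(list(to = e$from[i], p = pen[i])))
  }
  paths <- list()
  walk <- function(u, seen, acc) {
    if (u == target) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (x in nb[[u]]) {
      if (x$to %in% seen) next
      walk(x$to, c(seen, x$to), acc + x$p)
    }
  }
  if (source == target) return(list(min_penalty = 0, penalties = 0))
  walk(source, source, 0)
  pens <- unlist(paths)
  list(min_penalty = if (length(pens)) min(pens) else Inf,
       penalties = sort(pens))
}

# single-source variant: min penalty over all simple paths from `source`
# to every node, by one exhaustive depth-first traversal
oracle_min_penalties <- function(network, penalties, source) {
  e <- network$edges
  pen <- kbmine::penalty_for(penalties, e$class)
  nb <- list()
  for (i in seq_len(nrow(e))) {
    nb[[e$from[i]]] <- c(nb[[e$from[i]]], list(list(to = e$to[i], p = pen[i])))
    nb[[e$to[i]]] <- c(nb[[e$to[i]]], list(list(to = e$from[i], p = pen[i])))
  }
  best <- setNames(rep(Inf, nrow(network$nodes)), network$nodes$id)
  best[source] <- 0
  walk <- function(u, seen, acc) {
    for (x in nb[[u]]) {
      if (x$to %in% seen) next
      acc2 <- acc + x$p
      if (acc2 < best[x$to]) best[x$to] <<- acc2
      walk(x$to, c(seen, x$to), acc2)
    }
  }
  walk(source, source, 0)
  best
}

# --- random generators --------------------------------------------------

# random multi-ontology concept graph: a tree per prefix plus extra
# random edges and a few cross-prefix mappings
random_concept_graph <- function(n = 20, n_prefix = 2, extra = 3,
                                 p_map = 0.5) {
  prefixes <- paste0("P", seq_len(n_prefix))
  per <- ceiling(n / n_prefix)
  concepts <- NULL
  relations <- NULL
  for (pf in prefixes) {
    ids <- paste0(pf, ":c", seq_len(per))
    concepts <- c(concepts, ids)
    if (per > 1) {
      parent <- ids[vapply(2:per, function(i) sample.int(i - 1L, 1L), 0L)]
      relations <- rbind(relations, data.frame(
        subject = ids[2:per], predicate = "is_a", object = parent))
    }
  }
  for (k in seq_len(extra)) {
    ab <- sample(concepts, 2)
    relations <- rbind(relations, data.frame(
      subject = ab[1], predicate = "part_of", object = ab[2]))
  }
  if (n_prefix > 1 && stats::runif(1) < p_map) {
    ab <- c(sample(grep("^P1:", concepts, value = TRUE), 1),
            sample(grep("^P2:", concepts, value = TRUE), 1))
    relations <- rbind(relations, data.frame(
      subject = ab[1], predicate = "mapped_to", object = ab[2]))
  }
  concept_graph(data.frame(curie = concepts, label = ""), relations)
}

random_descriptor <- function(graph, id, n_elements,
                              p_unresolvable = 0.1) {
  pool <- graph$concepts$curie
  cur <- sample(pool, min(n_elements, length(pool)))
  if (stats::runif(1) < p_unresolvable) {
    cur[1] <- paste0("XX:stray", sample.int(1000, 1))
  }
  semantic_descriptor(id, cur)
}

# random typed network on <= n nodes with 2 penalty classes
random_typed_network <- function(n = 8, p_edge = 0.3) {
  ids <- paste0("v", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  edges <- NULL
  for (cls in c("lo", "hi")) {
    on <- stats::runif(nrow(pairs)) < p_edge / 2
    if (any(on)) {
      edges <- rbind(edges, data.frame(from = ids[pairs[on, 1]],
                                       to = ids[pairs[on, 2]],
                                       class = cls))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(from = ids[1], to = ids[2], class = "lo")
  }
  list(network = typed_network(ids, edges),
       penalties = penalty_table(c(lo = 1, hi = 3)))
}
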