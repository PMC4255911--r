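# All generators run under an isolated RNG scope so that a fixed seed
# yields byte-identical fixtures without disturbing the caller's RNG.
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

#' Synthetic multi-ontology fixture with known similarity expectations
#'
#' Builds `n_ontologies` rooted `is_a` trees with distinct prefixes
#' (`ONT1:`, `ONT2:`, ...), sprinkles `n_mappings` random `mapped_to`
#' edges between different ontologies, and constructs descriptor pairs at
#' controlled element distances — 0 (identical), 1, 2, and unreachable —
#' together with the similarity aggregates those planted distances imply.
#' Mapping edges never touch the concepts used in the planted pairs, so
#' the planted tree distances are the true graph distances. The
#' unreachable element uses a reserved prefix absent from the graph.
#'
#' Emulates the combinatorial use of orthogonal ontologies: descriptors
#' combine concepts from several trees exactly as model/clinical
#' parameter annotations combine substance, quality and anatomy terms.
#'
#' @param n_ontologies number of disjoint `is_a` trees (default 2).
#' @param depth tree depth (default 3).
#' @param branching children per node (default 2).
#' @param n_mappings inter-ontology `mapped_to` edges (default 5).
#' @param seed RNG seed (default 17).
#' @return list with `graph` (a [concept_graph()]) and `pairs`: a list of
#'   `list(query, target, expected)` where `expected` holds `sum_scores`,
#'   `coverage`, `total`, `normalized` implied by the planted distances.
#' @export
make_ontology_fixture <- function(n_ontologies = 2L, depth = 3L,
                                  branching = 2L, n_mappings = 5L,
                                  seed = 17L) {
  if (n_ontologies < 1L || depth < 1L || branching < 1L || n_mappings < 0L) {
    stop("n_ontologies, depth, branching must be >= 1; n_mappings >= 0",
         call. = FALSE)
  }
  with_fixture_seed(seed, {
    trees <- lapply(seq_len(n_ontologies), function(k) {
      prefix <- paste0("ONT", k)
      ids <- paste0(prefix, ":N", formatC(1L, width = 4, flag = "0"))
      parent <- character()  # parent curie per non-root node
      counter <- 1L
      level <- ids
      for (d in seq_len(depth)) {
        nxt <- character()
        for (p in level) {
          for (b in seq_len(branching)) {
            counter <- counter + 1L
            id <- paste0(prefix, ":N", formatC(counter, width = 4,
                                               flag = "0"))
            ids <- c(ids, id)
            parent[id] <- p
            nxt <- c(nxt, id)
          }
        }
        level <- nxt
      }
      list(prefix = prefix, ids = ids, parent = parent)
    })
    concepts <- data.frame(
      curie = unlist(lapply(trees, `[[`, "ids")),
      label = "")
    concepts$label <- paste("concept", seq_len(nrow(concepts)))
    relations <- do.call(rbind, lapply(trees, function(t) {
      data.frame(subject = names(t$parent), predicate = "is_a",
                 object = unname(t$parent))
    }))

    # planted descriptor pairs use a root-to-leaf chain of tree 1;
    # mapping edges are drawn from the remaining concepts only
    chain <- trees[[1]]$ids[1]
    repeat {
      kids <- names(trees[[1]]$parent)[trees[[1]]$parent ==
                                         chain[length(chain)]]
      if (!length(kids)) break
      chain <- c(chain, kids[[1]])
    }
    reserved <- chain

    if (n_mappings > 0L && n_ontologies >= 2L) {
      pool <- lapply(trees, function(t) setdiff(t$ids, reserved))
      maps <- do.call(rbind, lapply(seq_len(n_mappings), function(i) {
        ab <- sample.int(n_ontologies, 2L)
        data.frame(subject = sample(pool[[ab[1]]], 1L),
                   predicate = "mapped_to",
                   object = sample(pool[[ab[2]]], 1L))
      }))
      relations <- rbind(relations, maps)
    }
    graph <- concept_graph(concepts, relations)

    # chain[i] and chain[i+d] are exactly d steps apart (unique tree
    # path; mappings avoid the chain)
    far <- "ZZZ:UNREACHABLE1"  # not in graph: isolated, matches nothing
    mk <- function(id, curies) semantic_descriptor(id, curies)
    pair <- function(name, qcur, tcur, dists) {
      n <- length(qcur)
      matched <- sum(is.finite(dists))
      s <- sum(element_score(dists[is.finite(dists)]))
      cov <- matched / n
      list(query = mk(paste0(name, "_q"), qcur),
           target = mk(paste0(name, "_t"), tcur),
           expected = list(sum_scores = s, coverage = cov,
                           total = s * cov, normalized = s * cov / n),
           planted_steps = dists)
    }
    pairs <- list(
      identical = pair("identical", chain[1:2], chain[1:2], c(0, 0)))
    if (length(chain) >= 3L) {
      pairs$one_step <- pair("one_step", c(chain[1], chain[2]),
                             c(chain[1], chain[3]), c(0, 1))
      pairs$unreachable <- pair("unreachable",
                                c(chain[1], chain[2], far),
                                c(chain[1], chain[3]), c(0, 1, Inf))
    }
    if (length(chain) >= 4L) {
      pairs$two_step <- pair("two_step", chain[1:2],
                             c(chain[1], chain[4]), c(0, 2))
    }
    list(graph = graph, pairs = pairs, chain = chain, seed = seed)
  })
}

#' Synthetic typed network fixture
#'
#' Random undirected multigraph over `n_nodes` nodes: every unordered
#' node pair receives each edge class independently with its probability.
#' A random spanning tree of the lowest-penalty class is added first so
#' the network is always connected.
#'
#' @param n_nodes number of nodes (`>= 2`).
#' @param edge_classes data.frame with columns `class`, `p`
#'   (probability), `penalty`; default emulates a two-quality PPI
#'   network: high-confidence co-IP edges (penalty 1) and noisier
#'   two-hybrid edges (penalty 3).
#' @param seed RNG seed (default 17).
#' @return list with `network` ([typed_network()]) and `penalties`
#'   ([penalty_table()]).
#' @export
make_network_fixture <- function(n_nodes = 12L,
                                 edge_classes = data.frame(
                                   class = c("coIP", "Y2H"),
                                   p = c(0.15, 0.3),
                                   penalty = c(1, 3)),
                                 seed = 17L) {
  if (n_nodes < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  edge_classes <- as.data.frame(edge_classes, stringsAsFactors = FALSE)
  if (any(edge_classes$p < 0 | edge_classes$p > 1)) {
    stop("edge-class probabilities must be in [0, 1]", call. = FALSE)
  }
  if (any(edge_classes$penalty < 0)) {
    stop("penalties must be non-negative", call. = FALSE)
  }
  with_fixture_seed(seed, {
    ids <- paste0("n", formatC(seq_len(n_nodes), width = 2, flag = "0"))
    best_class <- edge_classes$class[which.min(edge_classes$penalty)]
    # random spanning tree: connect node i to a random earlier node
    tree <- data.frame(
      from = ids[vapply(seq_len(n_nodes - 1L) + 1L,
                        function(i) sample.int(i - 1L, 1L), 0L)],
      to = ids[seq_len(n_nodes - 1L) + 1L],
      class = best_class)
    pairs <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
    extra <- do.call(rbind, lapply(seq_len(nrow(edge_classes)), function(k) {
      on <- stats::runif(nrow(pairs)) < edge_classes$p[[k]]
      if (!any(on)) return(NULL)
      data.frame(from = ids[pairs[on, 1L]], to = ids[pairs[on, 2L]],
                 class = edge_classes$class[[k]])
    }))
    net <- typed_network(ids, rbind(tree, extra))
    list(network = net,
         penalties = penalty_table(
           setNames(edge_classes$penalty, edge_classes$class)),
         seed = seed)
  })
}

#' Synthetic pathway collection with planted groups
#'
#' Each planted group shares a disjoint core member set; every pathway in
#' the group is the core plus its own private random members, sized so
#' the Jaccard index between two group members is at least
#' `within_overlap`, while pathways from different groups overlap only by
#' chance (expected Jaccard near 0 for the default universe). This is the
#' regime in which redundant pathway entries from different source
#' databases describe the same biology under different names.
#'
#' @param n_groups planted groups (default 4).
#' @param pathways_per_group pathways per group (default 10).
#' @param universe_size identifier universe (default 2000).
#' @param within_overlap minimum within-group Jaccard in `(0, 1]`
#'   (default 0.5).
#' @param core_size shared members per group (default 40).
#' @param seed RNG seed (default 17).
#' @return list with `collection` ([pathway_collection()]) and `planted`
#'   (list of pathway-id vectors, the true grouping).
#' @export
make_pathway_fixture <- function(n_groups = 4L, pathways_per_group = 10L,
                                 universe_size = 2000L,
                                 within_overlap = 0.5, core_size = 40L,
                                 seed = 17L) {
  if (within_overlap <= 0 || within_overlap > 1) {
    stop("within_overlap must be in (0, 1]", call. = FALSE)
  }
  if (n_groups < 1L || pathways_per_group < 2L) {
    stop("need n_groups >= 1 and pathways_per_group >= 2", call. = FALSE)
  }
  if (n_groups * core_size > universe_size) {
    stop("universe_size too small for ", n_groups,
         " disjoint cores of size ", core_size, call. = FALSE)
  }
  # two members share the core: J = c / (c + 2p) >= w  =>  p <= c(1-w)/(2w)
  private <- floor(core_size * (1 - within_overlap) / (2 * within_overlap))
  with_fixture_seed(seed, {
    universe <- paste0("g", formatC(seq_len(universe_size), width = 6,
                                    flag = "0"))
    core_pool <- sample(universe, n_groups * core_size)
    rest <- setdiff(universe, core_pool)
    planted <- list()
    pathways <- list()
    for (g in seq_len(n_groups)) {
      core <- core_pool[((g - 1L) * core_size + 1L):(g * core_size)]
      ids <- paste0("G", g, "_P", seq_len(pathways_per_group))
      for (id in ids) {
        priv <- if (private > 0L) sample(rest, private) else character()
        pathways[[id]] <- list(description = paste("planted group", g),
                               members = c(core, priv))
      }
      planted[[g]] <- ids
    }
    list(collection = pathway_collection(pathways), planted = planted,
         seed = seed)
  })
}
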