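three_node_net <- function() {
  # direct low-quality edge vs a two-step high-quality route
  list(network = typed_network(
    c("A", "B", "C"),
    data.frame(from = c("A", "A", "C"), to = c("B", "C", "B"),
               class = c("Y2H", "coIP", "coIP"))),
    penalties = penalty_table(c(coIP = 1, Y2H = 3)))
}

test_that("typed networks canonicalize edges and create missing nodes", {
  net <- typed_network(data.frame(id = "g1", type = "gene"),
                       data.frame(from = c("g2", "g1", "g1"),
                                  to = c("g1", "g2", "g2"),
                                  class = c("coIP", "coIP", "Y2H")))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 2)  # duplicate (g1,g2,coIP) collapsed
  expect_true(all(net$edges$from <= net$edges$to))
})

test_that("penalty tables look up classes with a default fallback", {
  pt <- penalty_table(c(coIP = 1, Y2H = 3), default_penalty = 2)
  expect_equal(penalty_for(pt, c("coIP", "Y2H", "unknown")), c(1, 3, 2))
  expect_error(penalty_table(c(bad = -1)), "non-negative")
})

test_that("networks and penalties load from TSV with validation", {
  ef <- withr::local_tempfile(fileext = ".tsv")
  pf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\tcoIP\tgene|gene", "g2\td1\tassoc\tgene|disease"), ef)
  writeLines(c("coIP\t1"), pf)
  expect_warning(loaded <- load_typed_network(ef, pf, default_penalty = 2),
                 "assoc")
  expect_equal(nrow(loaded$network$nodes), 3)
  expect_equal(loaded$network$nodes$type[loaded$network$nodes$id == "d1"],
               "disease")
  expect_equal(penalty_for(loaded$penalties, "assoc"), 2)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(load_typed_network(empty), "empty edge table")
  writeLines(c("coIP\tnot_a_number"), pf)
  expect_error(load_typed_network(ef, pf), "non-numeric penalty")
})

test_that("the co-IP/two-hybrid example prefers the two-edge route", {
  x <- three_node_net()
  best <- penalized_search(x$network, x$penalties, "A", "B", mode = "best")
  expect_length(best, 1)
  expect_equal(best[[1]]$nodes, c("A", "C", "B"))
  expect_equal(best[[1]]$classes, c("coIP", "coIP"))
  expect_equal(best[[1]]$total_penalty, 2)

  below <- penalized_search(x$network, x$penalties, "A", "B",
                            mode = "all_below", threshold = 3)
  expect_length(below, 2)
  expect_equal(vapply(below, `[[`, 0, "total_penalty"), c(2, 3))
  expect_equal(below[[2]]$nodes, c("A", "B"))
})

test_that("search contract edge cases: identity, unknowns, thresholds", {
  x <- three_node_net()
  same <- penalized_search(x$network, x$penalties, "A", "A")
  expect_length(same, 1)
  expect_equal(same[[1]]$total_penalty, 0)
  expect_length(same[[1]]$classes, 0)
  expect_error(penalized_search(x$network, x$penalties, "A", "nope"),
               "unknown node")
  expect_error(penalized_search(x$network, x$penalties, "A", "B",
                                mode = "all_below"), "threshold")
  expect_error(penalized_search(x$network, x$penalties, "A", "B",
                                mode = "all_below", threshold = -1),
               "non-negative")
  # below-minimum threshold: no paths, exact minimum still reported
  none <- penalized_search(x$network, x$penalties, "A", "B",
                           mode = "all_below", threshold = 1)
  expect_length(none, 0)
  expect_equal(attr(none, "min_penalty"), 2)
})

test_that("truncation at max_paths is explicit, never silent", {
  # complete unit-penalty graph has many equal simple paths
  n <- 7
  ids <- paste0("k", 1:n)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  net <- typed_network(ids, data.frame(from = ids[pairs[, 1]],
                                       to = ids[pairs[, 2]],
                                       class = "e"))
  pt <- penalty_table(c(e = 1))
  res <- penalized_search(net, pt, "k1", "k7", mode = "all_below",
                          threshold = n, max_paths = 10)
  expect_length(res, 10)
  expect_true(attr(res, "truncated"))
})

test_that("minimal penalty matches exhaustive enumeration on random graphs", {
  set.seed(73)
  for (rep in 1:30) {
    x <- random_typed_network(n = sample(4:9, 1))
    ids <- x$network$nodes$id
    st <- sample(ids, 2)
    got <- penalized_search(x$network, x$penalties, st[1], st[2])
    want <- oracle_search(x$network, x$penalties, st[1], st[2])
    expect_equal(attr(got, "min_penalty"), want$min_penalty)
    if (length(got)) {
      expect_true(all(abs(vapply(got, `[[`, 0, "total_penalty") -
                            want$min_penalty) < 1e-9))
    }
    # all_below at the minimal penalty returns exactly the best set
    if (is.finite(want$min_penalty)) {
      below <- penalized_search(x$network, x$penalties, st[1], st[2],
                                mode = "all_below",
                                threshold = want$min_penalty)
      expect_equal(vapply(below, function(p) paste(p$nodes, collapse = "|"), ""),
                   vapply(got, function(p) paste(p$nodes, collapse = "|"), ""))
    }
  }
})

test_that("unit penalties reduce the search to BFS hop distance", {
  set.seed(91)
  for (rep in 1:20) {
    x <- random_typed_network(n = sample(4:9, 1))
    unit <- penalty_table(c(lo = 1, hi = 1))
    ids <- x$network$nodes$id
    g <- igraph::graph_from_data_frame(x$network$edges, directed = FALSE,
                                       vertices = ids)
    st <- sample(ids, 2)
    got <- attr(penalized_search(x$network, unit, st[1], st[2]),
                "min_penalty")
    hop <- igraph::distances(g, st[1], st[2])[1, 1]
    expect_equal(got, hop)
  }
})

test_that("raising a class penalty never lowers a minimal path penalty", {
  set.seed(101)
  for (rep in 1:10) {
    x <- random_typed_network(n = 7)
    ids <- x$network$nodes$id
    raised <- penalty_table(c(lo = 1, hi = 5))
    for (pair in 1:5) {
      st <- sample(ids, 2)
      a <- attr(penalized_search(x$network, x$penalties, st[1], st[2]),
                "min_penalty")
      b <- attr(penalized_search(x$network, raised, st[1], st[2]),
                "min_penalty")
      expect_gte(b, a - 1e-12)
    }
  }
})

test_that("path results round-trip through JSON", {
  x <- three_node_net()
  res <- penalized_search(x$network, x$penalties, "A", "B",
                          mode = "all_below", threshold = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_path_results(res, path)
  res2 <- read_path_results(path)
  expect_equal(length(res2), length(res))
  expect_equal(res2[[1]]$nodes, res[[1]]$nodes)
  expect_equal(attr(res2, "min_penalty"), attr(res, "min_penalty"))
})

test_that("node ranking combines min-max qualities and penalty", {
  x <- three_node_net()
  res <- penalized_search(x$network, x$penalties, "A", "B",
                          mode = "all_below", threshold = 3)
  # equal-penalty nodes ranked purely by quality: scores 1 and 0
  paths <- list(path_result(c("A", "C", "B"), c("e", "e"), 2),
                path_result(c("A", "D", "B"), c("e", "e"), 2))
  q <- data.frame(node_id = c("C", "D"), diseases = c(10, 2))
  r <- suppressWarnings(
    rank_nodes(paths, q, c(diseases = 1), weight_penalty = 1))
  expect_equal(r$node_id[1], "C")
  cd <- r[match(c("C", "D"), r$node_id), "combined_score"]
  expect_equal(cd, c(1, 0))

  # zero weights: ordering is by path penalty alone
  paths2 <- list(path_result(c("A", "C", "B"), c("e", "e"), 2),
                 path_result(c("A", "D", "B"), c("e", "e"), 5))
  r2 <- rank_nodes(paths2, q, c(diseases = 0), weight_penalty = 1)
  expect_lt(match("C", r2$node_id), match("D", r2$node_id))

  # singleton ranks first trivially; all-equal quality warns
  expect_equal(rank_nodes(paths[1], q, c(diseases = 1))$node_id[1], "A")
  qq <- data.frame(node_id = c("A", "B", "C", "D"), flat = c(3, 3, 3, 3))
  expect_warning(rank_nodes(paths, qq, c(flat = 1)), "all-equal")
})
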