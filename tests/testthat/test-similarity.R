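chain_graph <- function(n, prefix = "X") {
  # X:1 - X:2 - ... - X:n as an is_a chain
  rel <- data.frame(subject = paste0(prefix, ":", 2:n), predicate = "is_a",
                    object = paste0(prefix, ":", 1:(n - 1)))
  concept_graph(data.frame(curie = paste0(prefix, ":", 1:n), label = ""),
                rel)
}

test_that("element_score: 1 at zero steps, diminishing with distance", {
  expect_identical(element_score(0), 1)
  expect_equal(element_score(1), 0.5)
  expect_equal(element_score(3), 0.25)
  expect_true(all(diff(element_score(1:10)) < 0))
  # literal variant: plain reciprocal, tying 1-step with identity
  expect_identical(element_score(1, "literal"), 1)
  expect_equal(element_score(c(2, 4), "literal"), c(0.5, 0.25))
  expect_error(element_score(-1), "non-negative")
})

test_that("self-similarity is exactly 1 and worked two-element cases match", {
  g <- chain_graph(4)
  q <- semantic_descriptor("q", c("X:1", "X:3"))
  self <- match_descriptors(q, q, g)
  expect_identical(self$normalized, 1)
  expect_identical(self$coverage, 1)
  expect_true(all(self$element_matches$matched_via == "identical"))

  # {A, B} vs {A, C} with distance(B, C) = 1
  t1 <- semantic_descriptor("t1", c("X:1", "X:4"))
  m <- match_descriptors(q, t1, g)
  expect_equal(m$sum_scores, 1.5)
  expect_equal(m$coverage, 1)
  expect_equal(m$total, 1.5)
  expect_equal(m$normalized, 0.75)

  # {A, B, D} vs {A, C}, D unreachable
  q2 <- semantic_descriptor("q2", c("X:1", "X:3", "QQ:far"))
  m2 <- match_descriptors(q2, t1, g)
  expect_equal(m2$sum_scores, 1.5)
  expect_equal(m2$coverage, 2 / 3)
  expect_equal(m2$total, 1.0)
  expect_equal(m2$normalized, 1 / 3)
  expect_equal(
    m2$element_matches$matched_via[m2$element_matches$query_element == "QQ:far"],
    "unmatched")
})

test_that("matching agrees with the exhaustive assignment oracle", {
  set.seed(23)
  for (rep in 1:40) {
    g <- random_concept_graph(n = sample(6:20, 1))
    q <- random_descriptor(g, "q", sample(1:4, 1))
    t <- random_descriptor(g, "t", sample(1:5, 1))
    got <- match_descriptors(q, t, g, max_steps = 3)
    want <- oracle_match(q, t, g, max_steps = 3)
    expect_equal(got$sum_scores, want$sum_scores, tolerance = 1e-9)
    expect_equal(got$coverage, want$coverage)
    expect_equal(got$total, want$total, tolerance = 1e-9)
  }
})

test_that("normalized stays in [0,1]; 1 only for complete identical matching", {
  set.seed(31)
  for (rep in 1:30) {
    g <- random_concept_graph(n = 12)
    q <- random_descriptor(g, "q", sample(1:4, 1))
    t <- random_descriptor(g, "t", sample(1:4, 1))
    m <- match_descriptors(q, t, g)
    expect_gte(m$normalized, 0)
    expect_lte(m$normalized, 1 + 1e-12)
    if (m$normalized == 1) {
      expect_true(all(m$element_matches$matched_via == "identical"))
    }
  }
})

test_that("moving a target element one step farther never raises the score", {
  g <- chain_graph(6)
  q <- semantic_descriptor("q", c("X:1", "X:2"))
  norm <- vapply(3:6, function(k) {
    match_descriptors(
      q, semantic_descriptor("t", c("X:1", paste0("X:", k))), g,
      max_steps = 10)$normalized
  }, 0)
  expect_true(all(diff(norm) <= 1e-12))
})

test_that("coverage and normalized are non-decreasing in max_steps", {
  set.seed(57)
  for (rep in 1:15) {
    g <- random_concept_graph(n = 12)
    q <- random_descriptor(g, "q", 3)
    t <- random_descriptor(g, "t", 3)
    res <- lapply(0:4, function(ms) match_descriptors(q, t, g,
                                                      max_steps = ms))
    expect_true(all(diff(vapply(res, `[[`, 0, "coverage")) >= -1e-12))
    expect_true(all(diff(vapply(res, `[[`, 0, "normalized")) >= -1e-12))
  }
})

test_that("direction matters when descriptor sizes differ (documented)", {
  g <- chain_graph(4)
  q <- semantic_descriptor("q", c("X:1"))
  t <- semantic_descriptor("t", c("X:1", "X:4"))
  expect_equal(match_descriptors(q, t, g)$normalized, 1)
  expect_lt(match_descriptors(t, q, g)$normalized, 1)
})

test_that("identical and similar internal edges contribute to the score", {
  g <- chain_graph(4)
  q <- semantic_descriptor("q", c("X:1", "X:3"),
                           data.frame(from = "X:1", to = "X:3",
                                      class = "regulates"))
  # identical edge
  self <- match_descriptors(q, q, g)
  expect_equal(nrow(self$edge_matches), 1)
  expect_equal(self$edge_matches$score, 1)
  expect_identical(self$normalized, 1)
  # endpoint one step off, same class: score 1/(1 + 0 + 1) = 0.5
  t <- semantic_descriptor("t", c("X:1", "X:4"),
                           data.frame(from = "X:1", to = "X:4",
                                      class = "regulates"))
  m <- match_descriptors(q, t, g)
  expect_equal(m$edge_matches$score, 0.5)
  expect_equal(m$edge_matches$matched_via, "similar")
  # class mismatch adds one step: 1/(1 + 0 + 1 + 1) = 1/3
  t2 <- semantic_descriptor("t2", c("X:1", "X:4"),
                            data.frame(from = "X:1", to = "X:4",
                                       class = "binds"))
  m2 <- match_descriptors(q, t2, g)
  expect_equal(m2$edge_matches$score, 1 / 3)
  # aggregates per the contract: 3 query objects (2 elements + 1 edge)
  expect_equal(m2$sum_scores, 1 + 0.5 + 1 / 3)
  expect_equal(m2$coverage, 1)
  expect_equal(m2$normalized, m2$total / 3)
  # edge with an unmatched endpoint cannot match
  t3 <- semantic_descriptor("t3", c("X:1", "ZZ:far"))
  m3 <- match_descriptors(q, t3, g)
  expect_equal(m3$edge_matches$matched_via, "unmatched")
  expect_equal(m3$coverage, 1 / 3)
})

test_that("rank_candidates orders by normalized score with id tie-break", {
  g <- chain_graph(5)
  q <- semantic_descriptor("q", "X:1")
  targets <- list(semantic_descriptor("t_same", "X:1"),
                  semantic_descriptor("t_one", "X:2"),
                  semantic_descriptor("t_two", "X:3"))
  ranked <- rank_candidates(q, targets, g, max_steps = 3)
  expect_equal(vapply(ranked, `[[`, "", "target_id"),
               c("t_same", "t_one", "t_two"))
  expect_equal(vapply(ranked, `[[`, 0, "normalized"), c(1, 0.5, 1 / 3))
  # a disjoint target ranks last with exactly 0
  targets$extra <- semantic_descriptor("a_disjoint", "YY:other")
  ranked2 <- rank_candidates(q, targets, g)
  expect_equal(ranked2[[4]]$normalized, 0)
  # ties broken by target id ascending
  targets2 <- list(semantic_descriptor("b", "X:1"),
                   semantic_descriptor("a", "X:1"))
  expect_equal(vapply(rank_candidates(q, targets2, g), `[[`, "",
                      "target_id"), c("a", "b"))
  expect_length(rank_candidates(q, targets, g, top_n = 2), 2)
  expect_error(rank_candidates(q, targets, g, top_n = 0), "top_n")
})

test_that("similarity tables carry scores and JSON match detail", {
  g <- chain_graph(3)
  q <- semantic_descriptor("q", c("X:1", "X:2"))
  tab <- similarity_table(rank_candidates(q, list(q), g))
  expect_equal(tab$normalized, 1)
  detail <- jsonlite::fromJSON(tab$matches[1])
  expect_equal(detail$query_element, c("X:1", "X:2"))
})
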