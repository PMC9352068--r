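test_that("cascade construction keeps tails, heads and multiplicity", {
  ev <- as_tweet_events(cascade_rows("t1", "A", c("B", "C")))
  hg <- build_hypergraph(ev)
  expect_equal(nrow(hg$cascades), 1L)
  expect_equal(hg$cascades$tail, "A")
  expect_setequal(hg$cascades$head[[1]], c("B", "C"))
  expect_equal(hg$cascades$head_size, 2L)

  # two tweets each retweeted once is NOT one tweet retweeted twice
  ev2 <- as_tweet_events(dplyr::bind_rows(
    cascade_rows("t1", "A", "B", day = 1),
    cascade_rows("t2", "A", "B", day = 2)
  ))
  hg2 <- build_hypergraph(ev2)
  expect_equal(nrow(hg2$cascades), 2L)
  expect_equal(hg2$cascades$head_size, c(1L, 1L))
  ev3 <- as_tweet_events(cascade_rows("t1", "A", c("B", "C")))
  expect_equal(build_hypergraph(ev3)$cascades$head_size, 2L)

  # an original nobody retweets contributes its node but no hyper-edge
  ev4 <- as_tweet_events(ev_row("t1", "A", 1))
  hg4 <- build_hypergraph(ev4)
  expect_equal(nrow(hg4$cascades), 0L)
  expect_equal(hg4$nodes, "A")

  # duplicate retweets by one user collapse; self-retweets are dropped
  ev5 <- as_tweet_events(dplyr::bind_rows(
    ev_row("t1", "A", 1),
    ev_row("r1", "B", 1, TRUE, "t1"),
    ev_row("r2", "B", 2, TRUE, "t1"),
    ev_row("r3", "A", 2, TRUE, "t1")
  ))
  hg5 <- build_hypergraph(ev5)
  expect_equal(hg5$cascades$head[[1]], "B")

  # a retweet of an unseen root gets a synthetic orphan tail
  ev6 <- as_tweet_events(ev_row("r1", "B", 1, TRUE, "tX"))
  expect_message(hg6 <- build_hypergraph(ev6), "orphan|missing root")
  expect_equal(nrow(hg6$cascades), 1L)
  expect_true(any(grepl("orphan", hg6$nodes)))
})

test_that("the transition operator weights cascades by inverse head size", {
  hg <- build_hypergraph(as_tweet_events(two_hyperedge_events()))
  T <- transition_matrix(hg)
  expect_equal(T["A", "B"], 3 / 4)
  expect_equal(T["A", "C"], 1 / 4)

  hg1 <- build_hypergraph(as_tweet_events(cascade_rows("t1", "A", "B")))
  expect_equal(transition_matrix(hg1)["A", "B"], 1)

  # rows are stochastic on non-dangling nodes
  rs <- Matrix::rowSums(T)
  dang <- dangling_nodes(T)
  expect_true(all(abs(rs[!dang] - 1) < 1e-12))
})

test_that("unit head sizes reduce to the row-normalized retweet digraph", {
  withr::with_seed(21, {
    users <- paste0("u", 1:8)
    rows <- lapply(1:40, function(k) {
      p <- sample(users, 1)
      r <- sample(setdiff(users, p), 1)
      cascade_rows(paste0("t", k), p, r, day = k %% 10 + 1)
    })
    ev <- as_tweet_events(dplyr::bind_rows(rows))
  })
  Th <- transition_matrix(build_hypergraph(ev))
  Td <- digraph_transition(ev)
  expect_equal(as.matrix(Th)[rownames(Td), colnames(Td)], Td,
               tolerance = 1e-12)
})

test_that("the stationary distribution matches symmetry and a dense oracle", {
  hg <- build_hypergraph(as_tweet_events(two_cycle_events()))
  T <- transition_matrix(hg)
  p <- stationary_distribution(T, damping = 1)
  expect_equal(unname(p[c("A", "B")]), c(0.5, 0.5))

  # 3-node chain with teleport 0.15 against a dense eigen-decomposition
  ev <- as_tweet_events(dplyr::bind_rows(
    cascade_rows("t1", "A", "B"), cascade_rows("t2", "B", "C", day = 2)
  ))
  T3 <- transition_matrix(build_hypergraph(ev))
  p3 <- stationary_distribution(T3, damping = 0.85)
  expect_equal(unname(p3), unname(dense_stationary(T3, 0.85)),
               tolerance = 1e-8)
  expect_equal(sum(p3), 1, tolerance = 1e-12)

  # label permutation only permutes the result
  perm <- c(3, 1, 2)
  Tp <- T3[perm, perm]
  pp <- stationary_distribution(Tp, damping = 0.85)
  expect_equal(pp[rownames(T3)], p3[rownames(T3)], tolerance = 1e-9)
})

test_that("edge flow is the stationary step distribution", {
  hg <- build_hypergraph(as_tweet_events(two_cycle_events()))
  T <- transition_matrix(hg)
  p <- stationary_distribution(T, damping = 1)
  F <- edge_flow(T, p)
  expect_equal(F["A", "B"], 0.5)
  expect_equal(F["B", "A"], 0.5)
  expect_true(all(F@x >= 0))
  expect_equal(sum(F), 1, tolerance = 1e-9)

  # total edge mass is the stationary mass sitting on non-dangling nodes
  ev <- as_tweet_events(two_hyperedge_events())
  fs <- flow_state(build_hypergraph(ev), damping = 0.85)
  expect_equal(sum(fs$flow), sum(fs$p[!fs$dangling]), tolerance = 1e-9)
  expect_error(edge_flow(fs$T, fs$p[-1]), "different node sets")
})

test_that("empirical walk frequencies agree with the transition operator", {
  hg <- build_hypergraph(as_tweet_events(two_hyperedge_events()))
  T <- transition_matrix(hg)
  w <- simulate_hyper_walk(hg, n_walks = 2e4, n_steps = 3, seed = 7)
  for (v in unique(w$from)) {
    obs <- w[w$from == v, ]
    probs <- as.numeric(T[v, obs$to])
    if (length(probs) < 2) next
    expect_gt(chisq.test(obs$n, p = probs / sum(probs))$p.value, 0.01)
  }
  # every transition observed has positive model probability
  expect_true(all(T[cbind(w$from, w$to)] > 0))
})

test_that("restriction rebuilds edges but keeps the node set", {
  ev <- as_tweet_events(two_hyperedge_events())
  hg <- build_hypergraph(ev)
  # identity restriction
  same <- restrict_hypergraph(hg, ev)
  expect_equal(nrow(same$cascades), nrow(hg$cascades))
  expect_equal(same$nodes, hg$nodes)
  # single-cascade restriction
  one <- restrict_hypergraph(hg, ev[ev$root_tweet_id == "t1", ])
  expect_equal(nrow(one$cascades), 1L)
  expect_equal(one$nodes, hg$nodes)
  # disjoint subset: no hyper-edges, flow ops refuse it
  none <- restrict_hypergraph(hg, ev[0, ])
  expect_equal(nrow(none$cascades), 0L)
  expect_error(transition_matrix(none), "no hyper-edges")
})
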