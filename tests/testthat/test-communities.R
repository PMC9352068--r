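# Exhaustive quality oracle: best bipartition of <= 10 nodes by enumeration.
best_bipartition_quality <- function(F, p) {
  n <- nrow(F)
  nodes <- rownames(F)
  best <- -Inf
  best_split <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    grp <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    part <- tibble::tibble(node = nodes, community = grp)
    q <- partition_quality(part, F, p)
    if (q > best) {
      best <- q
      best_split <- grp
    }
  }
  list(quality = best, split = best_split)
}

test_that("two weakly joined retweet cliques are split apart", {
  ev <- as_tweet_events(two_clique_events())
  fs <- flow_state(build_hypergraph(ev), damping = 0.85)
  part <- detect_communities(fs$T, fs$p, seed = 1)
  expect_equal(length(unique(part$community)), 2L)
  grp_a <- part$community[grepl("^a", part$node)]
  grp_b <- part$community[grepl("^b", part$node)]
  expect_equal(length(unique(grp_a)), 1L)
  expect_equal(length(unique(grp_b)), 1L)
  expect_false(unique(grp_a) == unique(grp_b))

  # the detected split attains the exhaustive-best bipartition quality
  oracle <- best_bipartition_quality(edge_flow(fs$T, fs$p), fs$p)
  expect_equal(attr(part, "quality"), oracle$quality, tolerance = 1e-12)
})

test_that("a single symmetric clique is not split", {
  ev <- as_tweet_events(two_clique_events(cross = FALSE))
  ev <- ev[grepl("^ta", ev$root_tweet_id), ]  # only the first clique
  fs <- flow_state(build_hypergraph(ev), damping = 0.85)
  F <- edge_flow(fs$T, fs$p)
  one <- tibble::tibble(node = rownames(F), community = 0L)
  q_one <- partition_quality(one, F, fs$p)
  # enumeration: no bipartition beats the single community
  oracle <- best_bipartition_quality(F, fs$p)
  expect_gte(q_one, oracle$quality - 1e-12)
  part <- detect_communities(fs$T, fs$p, seed = 1)
  expect_equal(length(unique(part$community)), 1L)
})

test_that("detection is deterministic given the seed and well labeled", {
  cfg <- synth_config(n_users = 120, block_sizes = rep(30L, 4),
                      assortativity = 0.9, tweet_rate = 0.3, days = 40,
                      alpha = 0, init_engaged = 0.01, seed = 13)
  ev <- simulate_cascades(cfg)
  fs <- flow_state(build_hypergraph(ev), damping = 0.85)
  p1 <- detect_communities(fs$T, fs$p, seed = 3)
  p2 <- detect_communities(fs$T, fs$p, seed = 3)
  expect_identical(p1$community, p2$community)
  # ids contiguous from 0, ordered by decreasing size
  sizes <- as.integer(table(p1$community))
  expect_equal(sort(unique(p1$community)), seq_along(sizes) - 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("a strongly assortative planted stream is recovered", {
  skip_if_not_installed("mclust")
  cfg <- synth_config(n_users = 240, block_sizes = rep(60L, 4),
                      assortativity = 0.9, tweet_rate = 0.25, days = 50,
                      alpha = 0, init_engaged = 0.01, seed = 17)
  ev <- simulate_cascades(cfg)
  fs <- flow_state(build_hypergraph(ev), damping = 0.85)
  part <- detect_communities(fs$T, fs$p, seed = 1)
  blocks <- attr(ev, "blocks")
  ari <- mclust::adjustedRandIndex(part$community, blocks[part$node])
  expect_gte(ari, 0.9)
})

test_that("partition quality beats the trivial partitions", {
  ev <- as_tweet_events(two_clique_events())
  fs <- flow_state(build_hypergraph(ev), damping = 0.85)
  F <- edge_flow(fs$T, fs$p)
  part <- detect_communities(fs$T, fs$p, seed = 1)
  nodes <- rownames(F)
  q_all <- partition_quality(tibble::tibble(node = nodes, community = 0L),
                             F, fs$p)
  q_sing <- partition_quality(
    tibble::tibble(node = nodes, community = seq_along(nodes)), F, fs$p
  )
  expect_gte(attr(part, "quality"), q_all)
  expect_gte(attr(part, "quality"), q_sing)
})

test_that("visit probability averages the stationary mass", {
  p <- setNames(rep(1 / 4, 4), c("A", "B", "C", "D"))
  part <- tibble::tibble(node = names(p), community = c(0L, 0L, 1L, 1L))
  vp <- visit_probability(part, p)
  expect_equal(vp$avg_visit, c(1 / 4, 1 / 4))
  # singleton community reports exactly its node's mass
  p2 <- setNames(c(0.7, 0.2, 0.1), c("A", "B", "C"))
  part2 <- tibble::tibble(node = names(p2), community = c(0L, 1L, 2L))
  expect_equal(visit_probability(part2, p2)$avg_visit, c(0.7, 0.2, 0.1))
  # hand-built two-community case
  p3 <- setNames(c(0.5, 0.3, 0.2), c("A", "B", "C"))
  part3 <- tibble::tibble(node = names(p3), community = c(0L, 0L, 1L))
  expect_equal(visit_probability(part3, p3)$avg_visit, c(0.4, 0.2))
  # stationary mass is fully accounted for
  vp3 <- visit_probability(part3, p3)
  expect_equal(sum(vp3$avg_visit * vp3$size), 1)
})

test_that("escape probability measures the outward step share", {
  hg <- build_hypergraph(as_tweet_events(two_cycle_events()))
  fs <- flow_state(hg, damping = 1)
  # one community covering everything cannot be escaped
  all_in <- tibble::tibble(node = fs$nodes, community = 0L)
  expect_equal(escape_probability(all_in, fs$flow, fs$p)$escape, 0)
  # singleton communities on a 2-cycle: every step leaves
  sing <- tibble::tibble(node = fs$nodes, community = c(0L, 1L))
  expect_equal(escape_probability(sing, fs$flow, fs$p)$escape, c(1, 1))
})

test_that("per-period flow matches the global summary on one period", {
  cfg <- synth_config(n_users = 60, block_sizes = rep(30L, 2),
                      assortativity = 0.85, tweet_rate = 0.3, days = 30,
                      alpha = 0, init_engaged = 0.02, seed = 23)
  ev <- simulate_cascades(cfg)
  fs <- flow_state(build_hypergraph(ev), damping = 0.85)
  part <- detect_communities(fs$T, fs$p, seed = 1)
  global <- flow_summary(part, fs)
  one <- per_period_flow(ev, part, breakpoints = NULL, damping = 0.85)
  expect_equal(one$avg_visit, global$avg_visit, tolerance = 1e-9)
  expect_equal(one$escape, global$escape, tolerance = 1e-9)
  expect_true(all(one$escape >= 0 & one$escape <= 1, na.rm = TRUE))
})

test_that("a block whose outward mixing doubles shows rising escape", {
  mix1 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  mix2 <- matrix(c(0.6, 0.4, 0.1, 0.9), 2, 2, byrow = TRUE)
  cfg <- synth_config(n_users = 80, block_sizes = rep(40L, 2),
                      mixing = mix1, tweet_rate = 0.3, days = 60,
                      alpha = 0, init_engaged = 0.02,
                      period_breaks = 31, period_mixing = list(mix1, mix2),
                      seed = 29)
  ev <- simulate_cascades(cfg)
  blocks <- attr(ev, "blocks")
  part <- tibble::tibble(node = names(blocks), community = unname(blocks) - 1L)
  fl <- per_period_flow(ev, part, breakpoints = 31, damping = 0.85)
  b0 <- fl[fl$community == 0, ]
  expect_gt(b0$escape[b0$period == "P2"], b0$escape[b0$period == "P1"])
})
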