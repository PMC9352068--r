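make_partition <- function(users, comms) {
  tibble::tibble(node = users, community = as.integer(comms))
}

test_that("joint usage counts restricted occurrences as a distribution", {
  # one community, one hashtag: everything is probability 1
  ev <- as_tweet_events(dplyr::bind_rows(
    ev_row("t1", "u1", 1, tags = "only"),
    ev_row("t2", "u2", 1, tags = "only")
  ))
  part <- make_partition(c("u1", "u2"), c(0, 0))
  ju <- joint_usage(ev, part, "hashtag")
  expect_equal(unname(ju$P[1, 1]), 1)
  expect_equal(unname(ju$P_i), 1)
  expect_equal(unname(ju$P_a), 1)

  # two communities with exclusive hashtags, equal volume: diagonal 1/2
  ev2 <- as_tweet_events(dplyr::bind_rows(
    ev_row("t1", "u1", 1, tags = "aa"), ev_row("t2", "u2", 1, tags = "aa"),
    ev_row("t3", "u3", 1, tags = "bb"), ev_row("t4", "u4", 1, tags = "bb")
  ))
  part2 <- make_partition(paste0("u", 1:4), c(0, 0, 1, 1))
  ju2 <- joint_usage(ev2, part2, "hashtag")
  expect_equal(unname(diag(ju2$P)), c(0.5, 0.5))
  expect_equal(sum(ju2$P), 1)
  # marginal consistency
  expect_equal(unname(rowSums(ju2$P)), unname(ju2$P_i))
  expect_equal(unname(colSums(ju2$P)), unname(ju2$P_a))

  # a retweet re-counts the item; duplicates inside one posting do not
  ev3 <- as_tweet_events(dplyr::bind_rows(
    ev_row("t1", "u1", 1, tags = c("aa", "aa")),
    ev_row("r1", "u2", 1, rt = TRUE, root = "t1", tags = "aa"),
    ev_row("t2", "u3", 1, tags = "bb")
  ))
  part3 <- make_partition(paste0("u", 1:3), c(0, 0, 1))
  ju3 <- joint_usage(ev3, part3, "hashtag")
  expect_equal(unname(ju3$P["0", "aa"]), 2 / 3)

  # vocabulary smaller than the requested top-K is used in full
  expect_message(joint_usage(ev2, part2, "hashtag", top_items = 50),
                 "using all")
})

test_that("over-usage is the deviation from independence", {
  # independent joint: scores vanish identically
  P <- outer(c(0.6, 0.4), c(0.3, 0.7))
  dimnames(P) <- list(c("0", "1"), c("x", "y"))
  ju <- structure(list(P = P, P_i = rowSums(P), P_a = colSums(P),
                       item_kind = "hashtag"), class = "usage_joint")
  expect_equal(max(abs(overusage(ju)$xi)), 0)

  # diagonal 2x2 joint with uniform marginals: +1/4 on, -1/4 off
  P2 <- matrix(c(0.5, 0, 0, 0.5), 2, dimnames = dimnames(P))
  ju2 <- structure(list(P = P2, P_i = rowSums(P2), P_a = colSums(P2),
                        item_kind = "hashtag"), class = "usage_joint")
  xi2 <- overusage(ju2)$xi
  expect_equal(unname(diag(xi2)), c(0.25, 0.25))
  expect_equal(xi2[1, 2], -0.25)
  expect_equal(sum(xi2), 0)
})

test_that("total over-usage is exactly zero on generated streams", {
  cfg <- synth_config(n_users = 80, block_sizes = rep(40L, 2),
                      assortativity = 0.85, tweet_rate = 0.3, days = 30,
                      alpha = 0, init_engaged = 0.02, seed = 31)
  ev <- simulate_cascades(cfg)
  blocks <- attr(ev, "blocks")
  part <- make_partition(names(blocks), unname(blocks) - 1L)
  for (kind in c("hashtag", "url")) {
    ou <- overusage(joint_usage(ev, part, kind, top_items = 8))
    expect_equal(sum(ou$xi), 0, tolerance = 1e-12)
  }
})

test_that("planted hashtag biases surface as positive scores", {
  # each block over-emits its own tag by factor 3; across seeds the planted
  # (block, tag) pairs must score positive nearly always
  hits <- 0
  total <- 0
  for (seed in 1:6) {
    cfg <- synth_config(n_users = 90, block_sizes = rep(30L, 3),
                        assortativity = 0.9, tweet_rate = 0.4, days = 40,
                        alpha = 0, init_engaged = 0.02,
                        hashtags = paste0("tag", 1:6), seed = 100 + seed)
    ev <- simulate_cascades(cfg)
    blocks <- attr(ev, "blocks")
    part <- make_partition(names(blocks), unname(blocks) - 1L)
    xi <- overusage(joint_usage(ev, part, "hashtag", top_items = 6))$xi
    for (b in 1:3) {
      total <- total + 1
      if (xi[as.character(b - 1), paste0("tag", b)] > 0) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("co-clustering recovers planted blocks and is stable", {
  # block-diagonal planted score matrix with two community blocks
  xi <- rbind(
    matrix(0.2, 3, 4), matrix(-0.2, 3, 4)
  ) + withr::with_seed(41, matrix(rnorm(24, sd = 1e-3), 6, 4))
  xi <- cbind(xi, -xi)  # two item blocks
  dimnames(xi) <- list(paste0("c", 1:6), paste0("h", 1:8))
  ou <- structure(list(xi = xi, item_kind = "hashtag"),
                  class = "overusage_matrix")
  cc <- cocluster(ou, n_community_groups = 2, n_item_groups = 2)
  g <- cc$community_groups$group
  expect_equal(length(unique(g[1:3])), 1L)
  expect_equal(length(unique(g[4:6])), 1L)
  expect_false(g[1] == g[4])
  gi <- cc$item_groups$group
  expect_false(gi[1] == gi[5])

  # duplicate rows land in the same group
  xi2 <- xi
  xi2[2, ] <- xi2[1, ]
  ou2 <- structure(list(xi = xi2, item_kind = "hashtag"),
                   class = "overusage_matrix")
  cc2 <- cocluster(ou2, n_community_groups = 2, n_item_groups = 2)
  expect_equal(cc2$community_groups$group[1], cc2$community_groups$group[2])

  # row permutation changes labels only, not the grouping structure
  perm <- c(4, 5, 6, 1, 2, 3)
  ou3 <- structure(list(xi = xi[perm, ], item_kind = "hashtag"),
                   class = "overusage_matrix")
  cc3 <- cocluster(ou3, n_community_groups = 2, n_item_groups = 2)
  g3 <- cc3$community_groups$group[match(rownames(xi), rownames(xi[perm, ]))]
  expect_equal(length(unique(paste(g, g3))), 2L)

  expect_error(cocluster(ou, n_community_groups = 99), "more community groups")
})

test_that("dendrograms export as parseable Newick trees", {
  skip_if_not_installed("ape")
  xi <- withr::with_seed(43, matrix(rnorm(20), 5, 4,
               dimnames = list(paste0("c", 1:5), paste0("h", 1:4))))
  ou <- structure(list(xi = xi, item_kind = "hashtag"),
                  class = "overusage_matrix")
  cc <- cocluster(ou, n_community_groups = 2, n_item_groups = 2)
  nwk <- dendrogram_newick(cc, "communities")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(xi))
})
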