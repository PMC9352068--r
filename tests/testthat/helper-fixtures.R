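# Small builders shared across the suite. Fixtures are constructed in code;
# nothing is read from disk unless a test writes it first.

ev_row <- function(id, user, day, rt = FALSE, root = id,
                   urls = character(), tags = character()) {
  tibble::tibble(
    tweet_id = id, user_id = user, day = as.integer(day), is_retweet = rt,
    root_tweet_id = root, urls = list(urls), hashtags = list(tags)
  )
}

# one original + its retweeters, all on one day
cascade_rows <- function(root_id, poster, retweeters, day = 1,
                         urls = character(), tags = character()) {
  dplyr::bind_rows(
    ev_row(root_id, poster, day, urls = urls, tags = tags),
    dplyr::bind_rows(lapply(seq_along(retweeters), function(k) {
      ev_row(paste0(root_id, "_rt", k), retweeters[k], day, rt = TRUE,
             root = root_id, urls = urls, tags = tags)
    }))
  )
}

# the worked transition example: e1 = <{A},{B,C}>, e2 = <{A},{B}>, closed
# by B->A and C->A cascades so the chain is ergodic
two_hyperedge_events <- function() {
  dplyr::bind_rows(
    cascade_rows("t1", "A", c("B", "C"), day = 1),
    cascade_rows("t2", "A", "B", day = 2),
    cascade_rows("t3", "B", "A", day = 3),
    cascade_rows("t4", "C", "A", day = 3)
  )
}

two_cycle_events <- function() {
  dplyr::bind_rows(
    cascade_rows("t1", "A", "B", day = 1),
    cascade_rows("t2", "B", "A", day = 2)
  )
}

# two internally complete retweet groups joined by one weak cross cascade
two_clique_events <- function(cross = TRUE) {
  members <- function(prefix) paste0(prefix, 1:5)
  rows <- list()
  for (grp in c("a", "b")) {
    us <- members(grp)
    for (k in seq_along(us)) {
      rows[[length(rows) + 1]] <- cascade_rows(
        paste0("t", grp, k), us[k], setdiff(us, us[k]),
        day = k + ifelse(grp == "b", 10, 0)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (cross) out <- dplyr::bind_rows(out, cascade_rows("tx", "a1", "b1", day = 20))
  out
}

# independent digraph route for head-size-1 cascades: plain edge counting
# and row normalization, no hyper-graph code involved
digraph_transition <- function(events) {
  orig <- events[!events$is_retweet, ]
  rts <- events[events$is_retweet, ]
  tail_u <- orig$user_id[match(rts$root_tweet_id, orig$tweet_id)]
  edges <- dplyr::count(tibble::tibble(from = tail_u, to = rts$user_id),
                        from, to)
  nodes <- sort(unique(events$user_id))
  T <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  T[cbind(edges$from, edges$to)] <- edges$n
  rs <- rowSums(T)
  T[rs > 0, ] <- T[rs > 0, , drop = FALSE] / rs[rs > 0]
  T
}

# dense oracle for the stationary distribution with teleport + dangling fix
dense_stationary <- function(T, damping) {
  T <- as.matrix(T)
  n <- nrow(T)
  rs <- rowSums(T)
  T[rs == 0, ] <- 1 / n
  M <- damping * T + (1 - damping) / n
  e <- eigen(t(M))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

expect_tibble_equal <- function(a, b) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         ignore_attr = TRUE)
}
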