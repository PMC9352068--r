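#' Build the directed retweet hyper-graph
#'
#' Each original tweet with at least one distinct retweeter becomes a
#' directed hyper-edge: the original poster is the tail (source of the
#' information) and the set of retweeting users is the head. Duplicate
#' retweets of the same root by the same user collapse to one head
#' membership, self-retweets are dropped, and originals that nobody retweets
#' contribute only their node. Retweets whose root tweet is absent from the
#' stream keep their head user and get a synthetic orphan tail node (policy
#' reported via a message).
#'
#' @param events Event tibble with originals and retweets linked by
#'   `root_tweet_id`.
#' @return A `retweet_hypergraph`: list with `cascades` (tibble
#'   `root_tweet_id`, `tail`, `day`, `head` list-column, `head_size`) and
#'   `nodes` (character vector of users, including head-only users).
#' @export
build_hypergraph <- function(events) {
  orig <- events[!events$is_retweet, , drop = FALSE]
  rts <- events[events$is_retweet, , drop = FALSE]
  root_user <- setNames(orig$user_id, orig$tweet_id)
  root_day <- setNames(orig$day, orig$tweet_id)
  nodes <- unique(events$user_id)
  cascades <- tibble(root_tweet_id = character(), tail = character(),
                     day = integer(), head = list(), head_size = integer())
  n_orphans <- 0L
  if (nrow(rts)) {
    grp <- split(seq_len(nrow(rts)), rts$root_tweet_id)
    rows <- lapply(names(grp), function(root) {
      idx <- grp[[root]]
      tail_u <- root_user[root]
      if (is.na(tail_u)) {
        tail_u <- paste0(".orphan:", root)
        day <- min(rts$day[idx])
      } else {
        day <- unname(root_day[root])
      }
      head_u <- setdiff(unique(rts$user_id[idx]), tail_u)
      if (length(head_u) == 0) return(NULL)
      tibble(root_tweet_id = root, tail = unname(tail_u),
             day = as.integer(day), head = list(head_u),
             head_size = length(head_u))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) cascades <- bind_rows(rows)
    orphans <- grep("^\\.orphan:", cascades$tail, value = TRUE)
    n_orphans <- length(orphans)
    if (n_orphans > 0) {
      inform(paste0(n_orphans, " cascade(s) with missing root tweet; ",
                    "synthetic tail nodes added"))
      nodes <- union(nodes, orphans)
    }
  }
  cascades <- cascades[order(cascades$day, cascades$root_tweet_id), , drop = FALSE]
  structure(
    list(cascades = cascades, nodes = sort(nodes)),
    class = "retweet_hypergraph", n_orphans = n_orphans
  )
}

#' @export
print.retweet_hypergraph <- function(x, ...) {
  cat("<retweet_hypergraph> ", length(x$nodes), " nodes, ",
      nrow(x$cascades), " hyper-edges\n", sep = "")
  invisible(x)
}

#' Rebuild a hyper-graph from an event subset, keeping the full node set
#'
#' Used for content-restricted and per-period analyses: hyper-edges are
#' rebuilt from the subset only, while the node set is retained from the
#' full graph so that a community partition computed on the full graph
#' remains applicable. An empty subset yields an edge-less hyper-graph
#' (downstream flow operators refuse it).
#'
#' @param hg A `retweet_hypergraph` built on the full stream.
#' @param events A subset of the original events.
#' @return A `retweet_hypergraph` on the original node set.
#' @export
restrict_hypergraph <- function(hg, events) {
  sub <- build_hypergraph(events)
  sub$nodes <- sort(union(hg$nodes, sub$nodes))
  sub
}

#' Random-walk transition operator of the hyper-graph
#'
#' The walk sits on a node, picks one of the hyper-edges incident to its
#' tail uniformly, then lands on one of the head nodes uniformly. The
#' resulting node-to-node operator is
#' \deqn{T_{i \to j} = \frac{\sum_{\alpha \in E(i,j)} |\alpha|^{-1}}
#'   {\sum_{k, \alpha \in E(i,k)} |\alpha|^{-1}}}
#' with `E(i,j)` the hyper-edges with tail `i` and head containing `j` and
#' `|alpha|` the head size. Rows of nodes with no outgoing hyper-edge are
#' zero (dangling).
#'
#' @param hg A `retweet_hypergraph` with at least one hyper-edge.
#' @return A sparse row-stochastic matrix (`dgCMatrix`) with node dimnames;
#'   dangling rows sum to zero (see [dangling_nodes()]).
#' @export
transition_matrix <- function(hg) {
  if (nrow(hg$cascades) == 0) abort("hyper-graph has no hyper-edges")
  nodes <- hg$nodes
  n <- length(nodes)
  hs <- hg$cascades$head_size
  i <- rep(match(hg$cascades$tail, nodes), hs)
  j <- match(unlist(hg$cascades$head), nodes)
  x <- rep(1 / hs, hs)
  T <- sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                    dimnames = list(nodes, nodes))
  rs <- rowSums(T)
  nz <- rs > 0
  T[nz, ] <- T[nz, , drop = FALSE] / rs[nz]
  T
}

#' Nodes with no outgoing hyper-edge
#'
#' @param T Transition matrix from [transition_matrix()].
#' @return Named logical vector, `TRUE` for dangling nodes.
#' @export
dangling_nodes <- function(T) {
  rs <- rowSums(T)
  setNames(rs < .Machine$double.eps, rownames(T))
}

#' Stationary distribution of the hyper-graph walk
#'
#' Power iteration on the effective transition operator, with dangling rows
#' completed uniformly and mixed with uniform teleportation at rate
#' `1 - damping` (damping 1 is allowed on ergodic graphs). Convergence is
#' declared when the L1 change falls below `tol`.
#'
#' @param T Row-stochastic sparse matrix from [transition_matrix()].
#' @param damping Probability of following the walk rather than teleporting
#'   (default 0.85).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Named numeric vector `p` summing to 1.
#' @export
stationary_distribution <- function(T, damping = 0.85, tol = 1e-10,
                                    max_iter = 10000) {
  n <- nrow(T)
  dang <- dangling_nodes(T)
  Tt <- Matrix::t(T)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    pn <- as.numeric(Tt %*% p) + sum(p[dang]) / n
    pn <- damping * pn + (1 - damping) / n
    pn <- pn / sum(pn)
    res <- sum(abs(pn - p))
    p <- pn
    if (res < tol) {
      return(setNames(p, rownames(T)))
    }
  }
  abort(paste0("stationary distribution did not converge after ", max_iter,
               " iterations (L1 residual ", format(res), ")"))
}

#' Steady-state edge flow
#'
#' The probability of observing a walk step from node `j` to node `i` at
#' stationarity, `p(i, j) = T_{j -> i} p(j)`. The total flow mass equals the
#' stationary mass on non-dangling nodes (teleportation only regularizes
#' `p`; it carries no edge); the marginal `sum_j p(i, j)` is the visit
#' probability of `i` through actual edges.
#'
#' @param T Transition matrix.
#' @param p Stationary distribution on the same node set.
#' @return Sparse matrix `F` with `F[i, j] = p(i, j)`.
#' @export
edge_flow <- function(T, p) {
  if (length(p) != nrow(T)) abort("p and T have different node sets")
  F <- Matrix::t(Diagonal(x = as.numeric(p)) %*% T)
  dimnames(F) <- dimnames(T)
  F
}

#' One-call flow state of a hyper-graph
#'
#' Convenience wrapper computing the transition operator, its stationary
#' distribution and the steady-state edge flow.
#'
#' @inheritParams stationary_distribution
#' @param hg A `retweet_hypergraph`.
#' @return A `flow_state` list: `T`, `p`, `flow`, `nodes`, `dangling`,
#'   `damping`.
#' @export
flow_state <- function(hg, damping = 0.85, tol = 1e-10, max_iter = 10000) {
  T <- transition_matrix(hg)
  p <- stationary_distribution(T, damping = damping, tol = tol,
                               max_iter = max_iter)
  structure(
    list(T = T, p = p, flow = edge_flow(T, p), nodes = rownames(T),
         dangling = dangling_nodes(T), damping = damping),
    class = "flow_state"
  )
}

#' @export
print.flow_state <- function(x, ...) {
  cat("<flow_state> ", length(x$nodes), " nodes, damping ", x$damping,
      ", ", sum(x$dangling), " dangling\n", sep = "")
  invisible(x)
}

#' Simulate the hyper-graph random walk directly
#'
#' Literal simulation of the walk defining the transition operator: from the
#' current node choose an incident hyper-edge (by tail) uniformly, then a
#' head node uniformly. Used as an independent oracle for
#' [transition_matrix()]. Walks that reach a dangling node stop early.
#'
#' @param hg A `retweet_hypergraph`.
#' @param n_walks Number of independent walks.
#' @param n_steps Steps per walk (default 3).
#' @param seed Integer seed (the global RNG state is preserved).
#' @return A tibble of observed transitions with columns `from`, `to`, `n`.
#' @export
simulate_hyper_walk <- function(hg, n_walks = 1e5, n_steps = 3, seed = 1L) {
  nodes <- hg$nodes
  inc <- split(seq_len(nrow(hg$cascades)), hg$cascades$tail)
  heads <- hg$cascades$head
  withr::with_seed(seed, {
    starts <- names(inc)[sample.int(length(inc), n_walks, replace = TRUE)]
    cur <- starts
    trans_from <- character(0)
    trans_to <- character(0)
    for (s in seq_len(n_steps)) {
      has_out <- cur %in% names(inc)
      active <- which(has_out)
      if (length(active) == 0) break
      nxt <- rep(NA_character_, length(cur))
      by_node <- split(active, cur[active])
      for (v in names(by_node)) {
        w <- by_node[[v]]
        edges <- inc[[v]]
        ce <- edges[sample.int(length(edges), length(w), replace = TRUE)]
        nxt[w] <- vapply(ce, function(e) {
          h <- heads[[e]]
          h[sample.int(length(h), 1L)]
        }, character(1))
      }
      trans_from <- c(trans_from, cur[active])
      trans_to <- c(trans_to, nxt[active])
      cur <- nxt
      cur[is.na(cur)] <- ".stopped"
    }
    count(tibble(from = trans_from, to = trans_to), .data$from, .data$to)
  })
}
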