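#' @name communities
#' @title Flow-based community detection and information-flow diagnostics
#'
#' @description
#' Communities are groups of users among which the hyper-graph random walk
#' recirculates: the partition maximizes the one-step auto-covariance of the
#' flow,
#' \deqn{Q = \sum_C \sum_{i,j \in C} \left[ p(i,j) - p(i) p(j) \right],}
#' the directed analogue of modularity with stationary-distribution weights
#' (stability at unitary Markov time). Per community the *average visit
#' probability* `p(C)/|C|` measures per-capita participation in the flow and
#' the *escape probability* `p(C-bar|C)` the tendency of the walk to leave:
#' low escape with high internal flow is the signature of an echo chamber.
NULL

# Greedy multi-level (Louvain-style) maximization of
#   Q = sum_C [ w_in(C) - P(C)^2 ]
# on the symmetrized flow W = F + t(F) (so w_in counts each directed pair
# once), with node mass m = stationary p. Deterministic given `seed`: node
# sweep order is a seeded shuffle, ties go to the lowest community id.
.louvain_level <- function(W, m) {
  n <- nrow(W)
  comm <- seq_len(n)
  Ptot <- as.numeric(m)
  Wp <- W@p
  Wi <- W@i
  Wx <- W@x
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (v in sample.int(n)) {
      ptr <- (Wp[v] + 1L):Wp[v + 1L]
      if (Wp[v + 1L] == Wp[v]) next
      nb <- Wi[ptr] + 1L
      wx <- Wx[ptr]
      keep <- nb != v
      nb <- nb[keep]
      wx <- wx[keep]
      c0 <- comm[v]
      Ptot[c0] <- Ptot[c0] - m[v]
      cand <- comm[nb]
      k_vc <- rowsum(wx, cand)
      ids <- as.integer(rownames(k_vc))
      if (!c0 %in% ids) {
        ids <- c(ids, c0)
        k_vc <- c(as.numeric(k_vc), 0)
      } else {
        k_vc <- as.numeric(k_vc)
      }
      gain <- k_vc - 2 * m[v] * Ptot[ids]
      best <- ids[order(-gain, ids)][1]
      if (gain[ids == best] <= gain[ids == c0] + 1e-15) best <- c0
      Ptot[best] <- Ptot[best] + m[v]
      if (best != c0) {
        comm[v] <- best
        improved <- TRUE
      }
    }
  }
  comm
}

.louvain <- function(W, m) {
  n0 <- nrow(W)
  membership <- seq_len(n0)
  repeat {
    comm <- .louvain_level(W, m)
    labels <- sort(unique(comm))
    if (length(labels) == nrow(W)) break
    relab <- match(comm, labels)
    S <- sparseMatrix(i = seq_along(relab), j = relab, x = 1,
                      dims = c(length(relab), length(labels)))
    W <- methods::as(Matrix::t(S) %*% W %*% S, "CsparseMatrix")
    m <- as.numeric(Matrix::t(S) %*% m)
    membership <- relab[membership]
    if (length(labels) == 1) break
  }
  membership
}

#' Detect flow communities of the hyper-graph walk
#'
#' Greedy multi-level maximization of the one-step flow auto-covariance
#' `Q = sum_C sum_{i,j in C} [p(i,j) - p(i)p(j)]` at unitary resolution.
#' Deterministic given `seed` (seeded node-sweep shuffles, ties broken by
#' lowest community id). Communities are relabeled by decreasing size with
#' contiguous ids starting at 0.
#'
#' @param T Transition matrix from [transition_matrix()].
#' @param p Stationary distribution from [stationary_distribution()].
#' @param seed Integer seed controlling the sweep order.
#' @return A `community_partition` tibble with columns `node`, `community`
#'   and attributes `quality` (the achieved Q) and `sizes`.
#' @export
detect_communities <- function(T, p, seed = 1L) {
  F <- edge_flow(T, p)
  W <- methods::as(F + Matrix::t(F), "CsparseMatrix")
  membership <- withr::with_seed(seed, .louvain(W, as.numeric(p)))
  # relabel by decreasing size; ties by smallest member index
  first_member <- tapply(seq_along(membership), membership, min)
  sizes <- table(membership)
  ord <- order(-as.integer(sizes), as.integer(first_member))
  new_id <- setNames(seq_along(ord) - 1L, names(sizes)[ord])
  community <- unname(new_id[as.character(membership)])
  part <- tibble(node = rownames(T), community = as.integer(community))
  attr(part, "sizes") <- as.integer(table(part$community))
  attr(part, "quality") <- partition_quality(part, F, p)
  class(part) <- c("community_partition", class(part))
  part
}

.community_of <- function(partition, nodes) {
  partition$community[match(nodes, partition$node)]
}

#' Flow auto-covariance quality of a partition
#'
#' Evaluates `Q = sum_C [ sum_{i,j in C} p(i,j) - P(C)^2 ]` for any
#' partition, where `P(C)` is the stationary mass of `C`.
#'
#' @param partition A `community_partition` (or tibble with `node`,
#'   `community`).
#' @param flow Edge-flow matrix from [edge_flow()].
#' @param p Stationary distribution.
#' @return A single number.
#' @export
partition_quality <- function(partition, flow, p) {
  comm <- .community_of(partition, rownames(flow))
  tr <- Matrix::summary(flow)
  same <- comm[tr$i] == comm[tr$j]
  internal <- sum(tr$x[same & !is.na(same)])
  Pc <- tapply(as.numeric(p), comm, sum)
  internal - sum(Pc^2)
}

#' Average visit probability per community
#'
#' `p(C)/|C| = (1/|C|) sum_{i in C} p(i)`: the per-capita stationary mass of
#' a community, a proxy for its members' participation in the flow.
#'
#' @param partition A `community_partition`.
#' @param p Stationary distribution named by node.
#' @return A tibble with columns `community`, `size`, `avg_visit`.
#' @export
visit_probability <- function(partition, p) {
  pv <- as.numeric(p)[match(partition$node, names(p))]
  out <- tibble(community = partition$community, p = pv) %>%
    group_by(.data$community) %>%
    summarise(size = n(), avg_visit = sum(.data$p, na.rm = TRUE) / n()) %>%
    arrange(.data$community)
  out
}

#' Escape probability per community
#'
#' `p(C-bar|C) = sum_{i not in C, j in C} p(i,j) / sum_{k in C} p(k)`: the
#' conditional probability that a walk currently in `C` leaves it in one
#' step. Nodes outside the partition (e.g. orphan tails in a restricted
#' graph) count as outside every community. Communities with zero visit mass
#' get `NA`.
#'
#' @param partition A `community_partition`.
#' @param flow Edge-flow matrix.
#' @param p Stationary distribution on the same node set as `flow`.
#' @return A tibble with columns `community`, `escape`.
#' @export
escape_probability <- function(partition, flow, p) {
  nodes <- rownames(flow)
  comm <- .community_of(partition, nodes)
  tr <- Matrix::summary(flow)
  ci <- comm[tr$i]
  cj <- comm[tr$j]
  comms <- sort(unique(partition$community))
  out_mass <- vapply(comms, function(cc) {
    from_c <- !is.na(cj) & cj == cc
    leaving <- from_c & (is.na(ci) | ci != cc)
    sum(tr$x[leaving])
  }, numeric(1))
  mass <- vapply(comms, function(cc) {
    sum(as.numeric(p)[!is.na(comm) & comm == cc])
  }, numeric(1))
  tibble(
    community = comms,
    escape = ifelse(mass > 0, out_mass / mass, NA_real_)
  )
}

#' Visit and escape summary of a flow state
#'
#' @param partition A `community_partition`.
#' @param fs A `flow_state` from [flow_state()].
#' @param subgraph,period Optional labels carried into the output.
#' @return A `flow_summary` tibble: `community`, `size`, `avg_visit`,
#'   `escape`, `subgraph`, `period`.
#' @export
flow_summary <- function(partition, fs, subgraph = "all", period = "all") {
  vp <- visit_probability(partition, fs$p)
  ep <- escape_probability(partition, fs$flow, fs$p)
  out <- left_join(vp, ep, by = "community")
  out$subgraph <- subgraph
  out$period <- period
  class(out) <- c("flow_summary", class(out))
  out
}

.cut_periods <- function(days, breakpoints) {
  if (is.null(breakpoints) || length(breakpoints) == 0) {
    return(factor(rep("P1", length(days))))
  }
  breakpoints <- sort(as.integer(breakpoints))
  labs <- paste0("P", seq_len(length(breakpoints) + 1))
  cut(days, breaks = c(-Inf, breakpoints - 0.5, Inf), labels = labs)
}

#' Per-period, per-subgraph flow summaries against a fixed partition
#'
#' Splits the stream at the given breakpoints (each breakpoint day starts a
#' new period), optionally restricts to the events of each catalog category,
#' rebuilds the hyper-graph of every period/subgraph cell, recomputes its
#' stationary flow and evaluates visit and escape probabilities against the
#' fixed full-period partition. Cells with no cascades yield `NA` rows.
#' Breakpoints outside the stream range produce empty periods (warned).
#'
#' @param events Full event tibble.
#' @param partition `community_partition` from the full-period graph.
#' @param breakpoints Integer days (or `Date`s) starting new periods; `NULL`
#'   for a single period.
#' @param catalog Optional URL catalog; adds one subgraph per category next
#'   to `"all"`.
#' @param damping Teleportation damping for the per-cell flows.
#' @return A `flow_summary` tibble over all cells.
#' @export
per_period_flow <- function(events, partition, breakpoints = NULL,
                            catalog = NULL, damping = 0.85) {
  if (inherits(breakpoints, "Date")) breakpoints <- as.integer(breakpoints)
  per <- .cut_periods(events$day, breakpoints)
  if (!is.null(breakpoints) &&
      (any(breakpoints <= min(events$day)) || any(breakpoints > max(events$day)))) {
    warn("some breakpoints fall outside the stream range; empty periods possible")
  }
  subgraphs <- c("all", if (!is.null(catalog)) unique(catalog$category))
  full_nodes <- partition$node
  cells <- expand.grid(period = levels(per), subgraph = subgraphs,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    pd <- cells$period[k]
    sg <- cells$subgraph[k]
    ev <- events[per == pd, , drop = FALSE]
    if (sg != "all") ev <- classify_events(ev, catalog, sg)
    hg <- suppressMessages(build_hypergraph(ev))
    hg$nodes <- sort(union(full_nodes, hg$nodes))
    if (nrow(hg$cascades) == 0) {
      return(tibble(community = sort(unique(partition$community)),
                    size = NA_integer_, avg_visit = NA_real_,
                    escape = NA_real_, subgraph = sg, period = pd))
    }
    fs <- flow_state(hg, damping = damping)
    flow_summary(partition, fs, subgraph = sg, period = pd)
  })
  out <- bind_rows(res)
  class(out) <- c("flow_summary", class(out))
  out
}
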