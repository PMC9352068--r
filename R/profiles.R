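#' Joint community-item usage distribution
#'
#' Counts hashtag (or URL domain) occurrences over tweets and retweets — a
#' retweet re-counts its items, duplicates within one posting count once —
#' restricted to the `top_items` most frequent items and the
#' `top_communities` largest communities, and normalizes the restricted
#' counts to a joint distribution `P(i, a)`. Marginals `P(i)` (community
#' volume share) and `P(a)` (item share) are derived from the restricted
#' joint so that the over-usage score is a proper covariance-like quantity.
#'
#' @param events Event tibble.
#' @param partition `community_partition` covering the event users (events
#'   from users outside the partition are dropped with a message).
#' @param item_kind `"hashtag"` or `"url"`.
#' @param top_items Number of most frequent items kept (fewer are used, with
#'   a message, when the vocabulary is smaller).
#' @param top_communities Number of largest communities kept.
#' @return A `usage_joint` list: `P` (communities x items matrix), `P_i`,
#'   `P_a`, `item_kind`, `n_occurrences`.
#' @export
joint_usage <- function(events, partition, item_kind = c("hashtag", "url"),
                        top_items = 50, top_communities = 50) {
  item_kind <- match.arg(item_kind)
  col <- if (item_kind == "hashtag") "hashtags" else "urls"
  occ <- tibble(
    tweet_id = rep(events$tweet_id, lengths(events[[col]])),
    user_id = rep(events$user_id, lengths(events[[col]])),
    item = unlist(events[[col]])
  )
  occ <- distinct(occ)
  occ$community <- .community_of(partition, occ$user_id)
  n_drop <- sum(is.na(occ$community))
  if (n_drop > 0) {
    inform(paste0(n_drop, " occurrence(s) from users outside the partition dropped"))
    occ <- occ[!is.na(occ$community), , drop = FALSE]
  }
  if (nrow(occ) == 0) abort("no item occurrences to profile")
  item_counts <- sort(table(occ$item), decreasing = TRUE)
  k <- min(top_items, length(item_counts))
  if (k < top_items) {
    inform(paste0("only ", k, " distinct ", item_kind, "s present; using all"))
  }
  # ties at the count boundary resolved alphabetically for determinism
  items <- names(item_counts)[order(-as.integer(item_counts), names(item_counts))][seq_len(k)]
  csize <- table(.community_of(partition, partition$node))
  m <- min(top_communities, length(csize))
  comms <- as.integer(names(sort(csize, decreasing = TRUE))[seq_len(m)])
  comms <- sort(comms)
  occ <- occ[occ$item %in% items & occ$community %in% comms, , drop = FALSE]
  if (nrow(occ) == 0) abort("restriction left no occurrences")
  P <- matrix(0, nrow = length(comms), ncol = length(items),
              dimnames = list(as.character(comms), sort(items)))
  tab <- count(occ, .data$community, .data$item)
  P[cbind(as.character(tab$community), tab$item)] <- tab$n
  P <- P / sum(P)
  structure(
    list(P = P, P_i = rowSums(P), P_a = colSums(P), item_kind = item_kind,
         n_occurrences = nrow(occ)),
    class = "usage_joint"
  )
}

#' Over-usage score matrix
#'
#' The covariance-like score `xi_ia = P(i, a) - P(i) P(a)`: positive where a
#' community uses an item more than the independence expectation, negative
#' where less. Summing over the restricted sets gives exactly zero.
#'
#' @param joint A `usage_joint` from [joint_usage()].
#' @return An `overusage_matrix` list: `xi` (communities x items), `P_i`,
#'   `P_a`, `item_kind`.
#' @export
overusage <- function(joint) {
  xi <- joint$P - outer(joint$P_i, joint$P_a)
  structure(
    list(xi = xi, P_i = joint$P_i, P_a = joint$P_a,
         item_kind = joint$item_kind),
    class = "overusage_matrix"
  )
}

#' @export
print.overusage_matrix <- function(x, ...) {
  cat("<overusage_matrix> ", nrow(x$xi), " communities x ", ncol(x$xi), " ",
      x$item_kind, "s\n", sep = "")
  invisible(x)
}

#' Hierarchical co-clustering of the over-usage matrix
#'
#' Two independent agglomerative clusterings: communities on the rows of the
#' score matrix and items on its columns (Euclidean distance, configurable
#' linkage). Deterministic. Flat labels are cut at the configured group
#' counts.
#'
#' @param ou An `overusage_matrix`.
#' @param n_community_groups Number of flat community groups (default 7).
#' @param n_item_groups Number of flat item groups (default 2).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A `coclustering` list: `community_groups` and `item_groups`
#'   tibbles, plus the two `hclust` trees.
#' @export
cocluster <- function(ou, n_community_groups = 7, n_item_groups = 2,
                      linkage = "average") {
  xi <- ou$xi
  if (n_community_groups > nrow(xi)) {
    abort("more community groups requested than communities")
  }
  if (n_item_groups > ncol(xi)) abort("more item groups requested than items")
  hc_rows <- hclust(dist(xi), method = linkage)
  hc_cols <- hclust(dist(Matrix::t(xi)), method = linkage)
  structure(
    list(
      community_groups = tibble(
        community = rownames(xi),
        group = unname(cutree(hc_rows, k = n_community_groups))
      ),
      item_groups = tibble(
        item = colnames(xi),
        group = unname(cutree(hc_cols, k = n_item_groups))
      ),
      hc_communities = hc_rows, hc_items = hc_cols
    ),
    class = "coclustering"
  )
}

#' Export a co-clustering dendrogram as a Newick string
#'
#' @param cc A `coclustering`.
#' @param which `"communities"` or `"items"`.
#' @return A Newick-format character scalar (requires the `ape` package).
#' @export
dendrogram_newick <- function(cc, which = c("communities", "items")) {
  which <- match.arg(which)
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  hc <- if (which == "communities") cc$hc_communities else cc$hc_items
  ape::write.tree(ape::as.phylo(hc))
}
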