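#' Tidy an over-usage matrix into long format
#'
#' @param x An `overusage_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `community`, `item`, `score`.
#' @method tidy overusage_matrix
#' @export
tidy.overusage_matrix <- function(x, ...) {
  xi <- x$xi
  tibble(
    community = rep(rownames(xi), times = ncol(xi)),
    item = rep(colnames(xi), each = nrow(xi)),
    score = as.numeric(xi)
  )
}

#' Tidy a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return A plain tibble with columns `node`, `community`.
#' @method tidy community_partition
#' @export
tidy.community_partition <- function(x, ...) {
  tibble(node = x$node, community = x$community)
}

#' One-row summary of a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return A tibble with `n_nodes`, `n_communities`, `quality`,
#'   `largest_size`.
#' @method glance community_partition
#' @export
glance.community_partition <- function(x, ...) {
  sizes <- attr(x, "sizes")
  tibble(
    n_nodes = nrow(x),
    n_communities = length(unique(x$community)),
    quality = attr(x, "quality"),
    largest_size = if (length(sizes)) max(sizes) else NA_integer_
  )
}

#' One-row summary of an engagement series
#'
#' @param x An `engagement_series`.
#' @param ... Unused.
#' @return A tibble with the day range, peak engaged count, and median
#'   defined rates.
#' @method glance engagement_series
#' @export
glance.engagement_series <- function(x, ...) {
  tibble(
    n_days = nrow(x),
    max_engaged = max(x$E),
    max_active = max(x$N),
    median_alpha = median(x$alpha, na.rm = TRUE),
    median_beta = median(x$beta, na.rm = TRUE),
    median_R = median(x$R, na.rm = TRUE),
    tau = attr(x, "tau") %||% NA_real_
  )
}

#' @importFrom rlang %||%
NULL

#' Plot an engagement series
#'
#' Two stacked panels: engaged and active user counts, and the reproduction
#' number with the `R = 1` threshold.
#'
#' @param object An `engagement_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot engagement_series
#' @export
autoplot.engagement_series <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("day", "E", "N", "R")],
    c("E", "N", "R"),
    names_to = "series", values_to = "value"
  )
  df$panel <- ifelse(df$series == "R", "reproduction number", "users")
  hl <- tibble(panel = "reproduction number", y = 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(data = hl, ggplot2::aes(yintercept = .data$y),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL, colour = NULL)
}

#' Plot a flow summary
#'
#' Escape probability against average visit probability, one point per
#' community, faceted by subgraph and period — the mesoscale portrait that
#' separates echo chambers (high visit, low escape) from spreaders.
#'
#' @param object A `flow_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flow_summary
#' @export
autoplot.flow_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_visit, y = .data$escape,
                                   size = .data$size)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::facet_grid(period ~ subgraph) +
    ggplot2::labs(x = "average visit probability", y = "escape probability",
                  size = "community size")
}

#' Plot an over-usage matrix
#'
#' Heat map of the community-by-item scores, diverging around zero.
#'
#' @param object An `overusage_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overusage_matrix
#' @export
autoplot.overusage_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$community,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = object$item_kind, y = "community", fill = "score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
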