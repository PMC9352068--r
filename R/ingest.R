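#' Normalize URLs to their registered domain
#'
#' Reduces a URL to a site-level identifier: the scheme, a leading `www.`,
#' the port and everything from the first `/`, `?` or `#` onward are dropped
#' and the remainder is lower-cased. Seed lists of content sources are
#' site-level (e.g. `"childrenshealthdefense.org"`), so all matching happens
#' at this resolution.
#'
#' @param urls Character vector of URLs or bare domains.
#' @return Character vector of normalized domains (`NA` stays `NA`).
#' @examples
#' normalize_domain("https://www.Example.org/path?q=1")
#' @export
normalize_domain <- function(urls) {
  x <- tolower(trimws(as.character(urls)))
  x <- sub("^[a-z][a-z0-9+.-]*://", "", x)
  x <- sub("[/?#].*$", "", x)
  x <- sub(":[0-9]+$", "", x)
  x <- sub("^www\\.", "", x)
  x <- sub("\\.+$", "", x)
  x[!nzchar(x)] <- NA_character_
  x
}

.event_columns <- c(
  "tweet_id", "user_id", "day", "is_retweet", "root_tweet_id",
  "urls", "hashtags"
)

.split_multi <- function(x) {
  lapply(x, function(s) {
    if (is.null(s) || length(s) == 0 || all(is.na(s))) return(character())
    if (length(s) == 1 && is.character(s)) {
      s <- strsplit(s, ";", fixed = TRUE)[[1]]
    }
    s <- trimws(as.character(s))
    s[nzchar(s) & !is.na(s)]
  })
}

#' Coerce a data frame to the canonical tweet-event table
#'
#' Validates and normalizes a table of postings into the canonical event
#' format used throughout the package: one row per posting (original tweet or
#' retweet) with columns `tweet_id`, `user_id`, `day` (integer day index),
#' `is_retweet`, `root_tweet_id` (equal to `tweet_id` for originals), `urls`
#' (list of normalized domains) and `hashtags` (list of lower-cased tags).
#' A `date` column (ISO dates) is converted to an integer day index. Rows
#' missing a required field, or retweets missing their root id, are rejected
#' with a warning; the number of rejected rows is stored in the
#' `"n_rejected"` attribute. Events are returned sorted by day.
#'
#' @param df A data frame with the columns above (`urls`/`hashtags` may be
#'   `;`-separated strings or list columns; both are accepted).
#' @return A tibble of events sorted by `day`, with attribute `n_rejected`.
#' @export
as_tweet_events <- function(df) {
  df <- as_tibble(df)
  if (!"day" %in% names(df) && "date" %in% names(df)) {
    df$day <- as.integer(as.Date(df$date))
    df$date <- NULL
  }
  for (col in c("urls", "hashtags")) {
    if (!col %in% names(df)) df[[col]] <- replicate(nrow(df), character(), simplify = FALSE)
  }
  missing_cols <- setdiff(.event_columns, names(df))
  if (length(missing_cols)) {
    abort(paste0("event table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  df <- df[.event_columns]
  df$tweet_id <- as.character(df$tweet_id)
  df$user_id <- as.character(df$user_id)
  df$day <- suppressWarnings(as.integer(df$day))
  df$is_retweet <- as.logical(df$is_retweet)
  df$root_tweet_id <- as.character(df$root_tweet_id)
  df$urls <- .split_multi(df$urls)
  df$hashtags <- .split_multi(df$hashtags)

  ok <- !is.na(df$tweet_id) & !is.na(df$user_id) & !is.na(df$day) &
    !is.na(df$is_retweet)
  # retweets must carry their root; originals default to themselves
  needs_root <- df$is_retweet & (is.na(df$root_tweet_id) | !nzchar(df$root_tweet_id))
  ok <- ok & !needs_root
  df$root_tweet_id[!df$is_retweet & ok &
    (is.na(df$root_tweet_id) | !nzchar(df$root_tweet_id))] <-
    df$tweet_id[!df$is_retweet & ok &
      (is.na(df$root_tweet_id) | !nzchar(df$root_tweet_id))]
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(paste0(n_rejected, " malformed event record(s) rejected"))
  }
  df <- df[ok, , drop = FALSE]
  df$urls <- lapply(df$urls, function(u) unique(normalize_domain(u)[!is.na(normalize_domain(u))]))
  df$hashtags <- lapply(df$hashtags, function(h) unique(tolower(sub("^#", "", h))))
  df <- df[order(df$day), , drop = FALSE]
  attr(df, "n_rejected") <- n_rejected
  df
}

#' Read a tweet-event stream from disk
#'
#' Reads a chronological event stream in line-delimited JSON (one object per
#' line) or CSV (with `;`-separated `urls`/`hashtags` fields). Malformed
#' lines are counted, reported with a warning and skipped; the count is kept
#' in the `"n_rejected"` attribute of the result.
#'
#' @param path Path to the event file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return A tibble of events as produced by [as_tweet_events()].
#' @export
read_events <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("event file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(as_tweet_events(df))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- as_tweet_events(tibble(
      tweet_id = character(), user_id = character(), day = integer(),
      is_retweet = logical(), root_tweet_id = character()
    ))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  parsed <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  bad_json <- vapply(parsed, is.null, logical(1))
  rows <- lapply(parsed[!bad_json], function(p) {
    tibble(
      tweet_id = .chr1(p$tweet_id), user_id = .chr1(p$user_id),
      day = if (!is.null(p$day)) .chr1(p$day) else .chr1(p$date),
      is_retweet = .chr1(p$is_retweet), root_tweet_id = .chr1(p$root_tweet_id),
      urls = list(as.character(unlist(p$urls))),
      hashtags = list(as.character(unlist(p$hashtags)))
    )
  })
  df <- bind_rows(rows)
  if (nrow(df)) {
    if (any(grepl("-", df$day, fixed = TRUE))) {
      df$day <- as.integer(as.Date(df$day))
    } else {
      df$day <- suppressWarnings(as.integer(df$day))
    }
    df$is_retweet <- as.logical(df$is_retweet)
  }
  out <- suppressWarnings(as_tweet_events(df))
  n_rejected <- sum(bad_json) + attr(out, "n_rejected")
  if (n_rejected > 0) warn(paste0(n_rejected, " malformed line(s)/record(s) rejected"))
  attr(out, "n_rejected") <- n_rejected
  out
}

.chr1 <- function(x) if (is.null(x) || length(x) == 0) NA_character_ else as.character(x[[1]])

#' Write a tweet-event stream to disk
#'
#' Serializes events to line-delimited JSON or CSV in the format accepted by
#' [read_events()], so generated streams round-trip.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- events
    df$urls <- vapply(df$urls, paste, character(1), collapse = ";")
    df$hashtags <- vapply(df$hashtags, paste, character(1), collapse = ";")
    readr::write_csv(df, path, progress = FALSE)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(
      tweet_id = events$tweet_id[i], user_id = events$user_id[i],
      day = events$day[i], is_retweet = events$is_retweet[i],
      root_tweet_id = events$root_tweet_id[i],
      urls = as.list(events$urls[[i]]), hashtags = as.list(events$hashtags[[i]])
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the URL co-occurrence graph
#'
#' Two domains are connected when at least one user posted (tweet or retweet,
#' anywhere in the collection window) both of them; the edge weight is the
#' number of distinct users sharing both. Used to extend curated seed lists
#' of sources by neighborhood dilation.
#'
#' @param events Event tibble.
#' @return An undirected weighted [igraph][igraph::graph_from_data_frame]
#'   graph whose vertices are the domains appearing in `events`.
#' @export
build_url_cooccurrence <- function(events) {
  ud <- tibble(
    user_id = rep(events$user_id, lengths(events$urls)),
    domain = unlist(events$urls)
  )
  ud <- distinct(ud)
  domains <- sort(unique(ud$domain))
  if (nrow(ud) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  pairs <- inner_join(ud, ud, by = "user_id", relationship = "many-to-many")
  pairs <- pairs[pairs$domain.x < pairs$domain.y, c("user_id", "domain.x", "domain.y")]
  edges <- distinct(pairs) %>%
    count(.data$domain.x, .data$domain.y, name = "weight")
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = tibble(name = domains))
}

#' Dilate a seed set of domains to its graph neighborhood
#'
#' Returns the seeds together with all their 1-hop neighbors in the
#' co-occurrence graph. Seeds absent from the graph pass through unchanged;
#' no edge-weight threshold is applied.
#'
#' @param graph Co-occurrence graph from [build_url_cooccurrence()].
#' @param seeds Character vector of seed domains.
#' @return Character vector: `seeds` plus their neighbors, sorted.
#' @export
dilate_seed_set <- function(graph, seeds) {
  seeds <- unique(normalize_domain(seeds))
  seeds <- seeds[!is.na(seeds)]
  if (igraph::vcount(graph) == 0) return(sort(seeds))
  present <- intersect(seeds, igraph::V(graph)$name)
  if (length(present) == 0) return(sort(seeds))
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(graph, present),
    function(v) igraph::V(graph)$name[as.integer(v)]
  )))
  sort(union(seeds, nb))
}

#' Construct a URL category catalog
#'
#' A catalog maps each domain to exactly one content category (e.g.
#' `vaccine_critical` or `media`) and records whether it came from the
#' curated seed list or from co-occurrence dilation. Domains assigned to more
#' than one category are an error: categories must be disjoint.
#'
#' @param domain Character vector of domains.
#' @param category Character vector of category labels, same length.
#' @param provenance `"seed"` or `"dilated"`, recycled.
#' @return A tibble with columns `domain`, `category`, `provenance`.
#' @export
url_catalog <- function(domain, category, provenance = "seed") {
  domain <- normalize_domain(domain)
  cat <- tibble(
    domain = domain, category = as.character(category),
    provenance = rep_len(as.character(provenance), length(domain))
  )
  cat <- distinct(cat, .data$domain, .data$category, .keep_all = TRUE)
  if (anyDuplicated(cat$domain)) {
    dup <- cat$domain[duplicated(cat$domain)]
    abort(paste0("domains assigned to multiple categories: ",
                 paste(unique(dup), collapse = ", ")))
  }
  cat
}

#' Read a URL category catalog from CSV
#'
#' Expects columns `domain,category` and optionally `provenance`.
#'
#' @param path Path to a CSV file.
#' @return A catalog tibble, see [url_catalog()].
#' @export
read_url_catalog <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("domain", "category") %in% names(df))) {
    abort("URL catalog needs columns 'domain' and 'category'")
  }
  url_catalog(df$domain, df$category,
              if ("provenance" %in% names(df)) df$provenance else "seed")
}

#' Select the events of one content category
#'
#' Keeps the events whose URL set intersects the domains of the requested
#' catalog category. An event carrying URLs of several categories is kept in
#' each of the corresponding selections; events with no URLs are never
#' selected. Original/retweet status is preserved.
#'
#' @param events Event tibble.
#' @param catalog Catalog tibble from [url_catalog()].
#' @param category One of the category labels present in `catalog`.
#' @return The subset of `events` in stream order.
#' @export
classify_events <- function(events, catalog, category) {
  if (!category %in% catalog$category) {
    abort(paste0("unknown category '", category, "'; catalog has: ",
                 paste(unique(catalog$category), collapse = ", ")))
  }
  doms <- catalog$domain[catalog$category == category]
  keep <- vapply(events$urls, function(u) any(u %in% doms), logical(1))
  events[keep, , drop = FALSE]
}
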