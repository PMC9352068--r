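#' Validated configuration of an end-to-end run
#'
#' Collects every knob of the pipeline in one validated object, which
#' [run_all()] serializes into the output directory so a run can be
#' reproduced from its artifacts alone.
#'
#' @param out_dir Output directory (created if needed).
#' @param events Event tibble, or `NULL` to read from `events_path`.
#' @param events_path Path to an event stream readable by [read_events()].
#' @param catalog URL catalog tibble, or `NULL` to read `catalog_path`.
#' @param catalog_path Path to a `domain,category` CSV.
#' @param tau Engagement window (days).
#' @param damping Random-walk teleportation damping.
#' @param seed Seed for community detection.
#' @param breakpoints Days (integers or `Date`s) starting new periods.
#' @param top_items,top_communities Restriction sizes for the over-usage
#'   profiles.
#' @param n_community_groups,n_item_groups Flat group counts for the
#'   hashtag (resp. URL) co-clusterings.
#' @param peak_smooth_width,peak_threshold_quantile,peak_min_separation
#'   Settings of [detect_engagement_events()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       events = NULL, events_path = NULL,
                       catalog = NULL, catalog_path = NULL,
                       tau = 3, damping = 0.85, seed = 1L,
                       breakpoints = NULL,
                       top_items = 50, top_communities = 50,
                       n_community_groups = 7, n_item_groups = 2,
                       peak_smooth_width = 7,
                       peak_threshold_quantile = 0.9,
                       peak_min_separation = 7) {
  if (is.null(events) && is.null(events_path)) {
    abort("either events or events_path is required")
  }
  if (!is.null(events_path) && !file.exists(events_path)) {
    abort(paste0("events_path does not exist: ", events_path))
  }
  if (!is.null(catalog_path) && !file.exists(catalog_path)) {
    abort(paste0("catalog_path does not exist: ", catalog_path))
  }
  if (tau < 1) abort("tau must be >= 1")
  if (damping < 0 || damping > 1) abort("damping must be in [0, 1]")
  if (inherits(breakpoints, "Date")) breakpoints <- as.integer(breakpoints)
  structure(
    list(out_dir = out_dir, events = events, events_path = events_path,
         catalog = catalog, catalog_path = catalog_path, tau = tau,
         damping = damping, seed = as.integer(seed),
         breakpoints = breakpoints, top_items = top_items,
         top_communities = top_communities,
         n_community_groups = n_community_groups,
         n_item_groups = n_item_groups,
         peak_smooth_width = peak_smooth_width,
         peak_threshold_quantile = peak_threshold_quantile,
         peak_min_separation = peak_min_separation),
    class = "run_config"
  )
}

.write_series_csv <- function(df, path) {
  df <- as_tibble(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
    }
  }
  readr::write_csv(df, path, progress = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes ingest, per-category engagement estimation, hyper-graph
#' construction, community detection, restricted and per-period flow
#' summaries and over-usage profiling, writing every table to `out_dir`:
#' `daily_summary.csv` (volumes and per-category content shares),
#' `engagement_<category>.csv` and `peaks_<category>.csv`, `partition.csv`,
#' `flow_summary.csv`, `xi_hashtag.csv` / `xi_url.csv` with their flat
#' groups, and the serialized configuration `config.yaml`. Identical
#' configuration and seed reproduce identical outputs. Stage failures
#' propagate as errors naming the stage; outputs of completed stages are
#' retained. Breakpoints outside the stream collapse to a single period
#' with a warning.
#'
#' @param config A `run_config`.
#' @return Invisibly, a named list with the in-memory results and the paths
#'   written.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  events <- stage("ingest", {
    ev <- if (!is.null(config$events)) as_tweet_events(config$events) else
      read_events(config$events_path)
    if (nrow(ev) == 0) abort("empty event stream")
    ev
  })
  catalog <- stage("ingest", {
    if (!is.null(config$catalog)) config$catalog
    else if (!is.null(config$catalog_path)) read_url_catalog(config$catalog_path)
    else NULL
  })

  cfg_out <- config[setdiff(names(config), c("events", "catalog"))]
  cfg_out$breakpoints <- as.numeric(cfg_out$breakpoints)
  yaml::write_yaml(cfg_out, file.path(config$out_dir, "config.yaml"))
  paths$config <- file.path(config$out_dir, "config.yaml")

  breakpoints <- config$breakpoints
  if (!is.null(breakpoints) &&
      (all(breakpoints <= min(events$day)) || all(breakpoints > max(events$day)))) {
    warn("breakpoints outside the stream range; falling back to one period")
    breakpoints <- NULL
  }

  categories <- if (!is.null(catalog)) unique(catalog$category) else character()

  summary_tbl <- stage("summary", {
    daily <- count(events, .data$day, name = "n_events")
    for (cat in categories) {
      sub <- classify_events(events, catalog, cat)
      cc <- count(sub, .data$day, name = "n")
      daily[[paste0("share_", cat)]] <-
        ifelse(daily$n_events > 0,
               cc$n[match(daily$day, cc$day)] / daily$n_events, 0)
      daily[[paste0("share_", cat)]][is.na(daily[[paste0("share_", cat)]])] <- 0
    }
    daily$period <- as.character(.cut_periods(daily$day, breakpoints))
    .write_series_csv(daily, file.path(config$out_dir, "daily_summary.csv"))
    daily
  })
  paths$daily_summary <- file.path(config$out_dir, "daily_summary.csv")

  engagement <- list()
  peaks <- list()
  for (cat in categories) {
    engagement[[cat]] <- stage(paste0("engagement:", cat), {
      ser <- engagement_series(events, classify_events(events, catalog, cat),
                               tau = config$tau)
      .write_series_csv(ser, file.path(config$out_dir,
                                       paste0("engagement_", cat, ".csv")))
      ser
    })
    peaks[[cat]] <- stage(paste0("peaks:", cat), {
      pk <- detect_engagement_events(
        engagement[[cat]],
        smooth_width = config$peak_smooth_width,
        threshold_quantile = config$peak_threshold_quantile,
        min_separation = config$peak_min_separation
      )
      .write_series_csv(pk, file.path(config$out_dir,
                                      paste0("peaks_", cat, ".csv")))
      pk
    })
    paths[[paste0("engagement_", cat)]] <-
      file.path(config$out_dir, paste0("engagement_", cat, ".csv"))
    paths[[paste0("peaks_", cat)]] <-
      file.path(config$out_dir, paste0("peaks_", cat, ".csv"))
  }

  hg <- stage("hypergraph", suppressMessages(build_hypergraph(events)))
  fs <- stage("hypergraph", flow_state(hg, damping = config$damping))
  partition <- stage("communities",
                     detect_communities(fs$T, fs$p, seed = config$seed))
  .write_series_csv(partition, file.path(config$out_dir, "partition.csv"))
  paths$partition <- file.path(config$out_dir, "partition.csv")

  flows <- stage("flow", {
    fl <- per_period_flow(events, partition, breakpoints = breakpoints,
                          catalog = catalog, damping = config$damping)
    .write_series_csv(fl, file.path(config$out_dir, "flow_summary.csv"))
    fl
  })
  paths$flow_summary <- file.path(config$out_dir, "flow_summary.csv")

  profiles <- list()
  for (kind in c("hashtag", "url")) {
    has_items <- sum(lengths(events[[if (kind == "hashtag") "hashtags" else "urls"]])) > 0
    if (!has_items) next
    profiles[[kind]] <- stage(paste0("profiles:", kind), {
      ju <- suppressMessages(joint_usage(
        events, partition, item_kind = kind,
        top_items = config$top_items,
        top_communities = config$top_communities
      ))
      ou <- overusage(ju)
      ng <- min(config$n_community_groups, nrow(ou$xi))
      ni <- min(if (kind == "url") config$n_item_groups else
                  config$n_community_groups, ncol(ou$xi))
      cc <- cocluster(ou, n_community_groups = ng, n_item_groups = ni)
      .write_series_csv(tidy(ou),
                        file.path(config$out_dir, paste0("xi_", kind, ".csv")))
      .write_series_csv(cc$community_groups,
                        file.path(config$out_dir,
                                  paste0("groups_", kind, "_communities.csv")))
      .write_series_csv(cc$item_groups,
                        file.path(config$out_dir,
                                  paste0("groups_", kind, "_items.csv")))
      list(joint = ju, overusage = ou, coclustering = cc)
    })
    paths[[paste0("xi_", kind)]] <-
      file.path(config$out_dir, paste0("xi_", kind, ".csv"))
  }

  invisible(list(
    events = events, catalog = catalog, daily_summary = summary_tbl,
    engagement = engagement, peaks = peaks, hypergraph = hg,
    flow = fs, partition = partition, flow_summary = flows,
    profiles = profiles, paths = paths
  ))
}
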