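#' Configuration of the synthetic event-stream generator
#'
#' Builds and validates the configuration of a generator that emulates the
#' statistical structure of the real streams the pipeline targets: a panel
#' of users split into planted blocks, assortative retweet cascades with
#' heavy-tailed head sizes, SIS-driven adoption of a tagged URL category
#' with tunable engagement and disengagement rates, and community-biased
#' hashtag usage. Daily resolution throughout.
#'
#' @param n_users Total number of users.
#' @param block_sizes Integer vector of planted block sizes (must sum to
#'   `n_users`).
#' @param mixing Row-stochastic block mixing matrix: probability that a
#'   retweeter of a cascade posted by block `k` is drawn from each block.
#'   Defaults to `assortativity` on the diagonal and the rest spread evenly.
#' @param assortativity Diagonal weight used to build the default `mixing`.
#' @param category_mixing,media_mixing Optional content-specific overrides of
#'   `mixing` for cascades whose root carries a category (resp. media) URL.
#' @param tweet_rate Per-user daily probability of emitting a base original
#'   tweet.
#' @param head_size_mean Mean of the geometric cascade head-size
#'   distribution (zero-retweet originals are allowed and produce no
#'   hyper-edge).
#' @param alpha,beta Daily engagement (contact) and disengagement rates:
#'   scalars or length-`days` vectors. `alpha > 1` is an error (per-day
#'   probability scale); `beta * (tau - 1)` must stay below 1.
#' @param tau Engagement window in days (default 3).
#' @param days Stream length in days.
#' @param init_engaged Fraction of users engaged at day 1.
#' @param block_category_rate Optional per-block daily rate of planted
#'   category originals, bypassing the SIS adoption process (used for
#'   mesoscale fixtures with prescribed content geography).
#' @param category_urls,media_urls Character pools the generator attaches to
#'   category and media postings.
#' @param media_share Probability that a base original carries a media URL.
#' @param hashtags Hashtag vocabulary.
#' @param hashtag_bias Blocks x hashtags matrix of multiplicative emission
#'   biases (rows renormalized); defaults to factor `3` on one preferred tag
#'   per block, cycled.
#' @param period_breaks Optional integer days starting new periods.
#' @param period_mixing Optional list (one mixing matrix per period)
#'   overriding `mixing` in each period.
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   full configuration.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_users = 400,
                         block_sizes = NULL,
                         mixing = NULL,
                         assortativity = 0.8,
                         category_mixing = NULL,
                         media_mixing = NULL,
                         tweet_rate = 0.2,
                         head_size_mean = 3,
                         alpha = 0.3,
                         beta = 0.1,
                         tau = 3,
                         days = 100,
                         init_engaged = 0.01,
                         block_category_rate = NULL,
                         category_urls = paste0("critical", 1:4, ".example"),
                         media_urls = paste0("media", 1:6, ".example"),
                         media_share = 0.5,
                         hashtags = paste0("tag", 1:10),
                         hashtag_bias = NULL,
                         period_breaks = NULL,
                         period_mixing = NULL,
                         seed = 1L) {
  if (is.null(block_sizes)) {
    b <- 4L
    block_sizes <- rep(n_users %/% b, b)
    block_sizes[b] <- n_users - sum(block_sizes[-b])
  }
  nb <- length(block_sizes)
  if (sum(block_sizes) != n_users) abort("block sizes must sum to n_users")
  if (is.null(mixing)) {
    off <- if (nb > 1) (1 - assortativity) / (nb - 1) else 0
    mixing <- matrix(off, nb, nb)
    diag(mixing) <- if (nb > 1) assortativity else 1
  }
  check_mix <- function(mx, nm) {
    mx <- as.matrix(mx)
    if (!all(dim(mx) == c(nb, nb))) abort(paste0(nm, " must be ", nb, "x", nb))
    if (any(mx < 0) || any(abs(rowSums(mx) - 1) > 1e-8)) {
      abort(paste0("rows of ", nm, " must be probabilities summing to 1"))
    }
    mx
  }
  mixing <- check_mix(mixing, "mixing")
  if (!is.null(category_mixing)) category_mixing <- check_mix(category_mixing, "category_mixing")
  if (!is.null(media_mixing)) media_mixing <- check_mix(media_mixing, "media_mixing")
  alpha <- rep_len(as.numeric(alpha), days)
  beta <- rep_len(as.numeric(beta), days)
  if (any(alpha < 0) || any(beta < 0)) abort("alpha and beta must be non-negative")
  if (any(alpha > 1)) abort("alpha exceeds 1: not a per-day probability")
  if (any(beta * (tau - 1) >= 1)) {
    abort("beta * (tau - 1) must be below 1 (window-compensated hazard)")
  }
  if (is.null(hashtag_bias)) {
    hashtag_bias <- matrix(1, nb, length(hashtags))
    for (k in seq_len(nb)) {
      hashtag_bias[k, ((k - 1) %% length(hashtags)) + 1] <- 3
    }
  }
  if (!is.null(period_mixing)) {
    period_mixing <- lapply(period_mixing, check_mix, nm = "period_mixing")
  }
  structure(
    list(
      n_users = as.integer(n_users), block_sizes = as.integer(block_sizes),
      mixing = mixing, category_mixing = category_mixing,
      media_mixing = media_mixing, tweet_rate = tweet_rate,
      head_size_mean = head_size_mean, alpha = alpha, beta = beta,
      tau = as.integer(tau), days = as.integer(days),
      init_engaged = init_engaged,
      block_category_rate = block_category_rate,
      category_urls = category_urls, media_urls = media_urls,
      media_share = media_share, hashtags = hashtags,
      hashtag_bias = hashtag_bias, period_breaks = period_breaks,
      period_mixing = period_mixing, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

.user_ids <- function(n) sprintf("u%05d", seq_len(n))

.user_blocks <- function(config) {
  rep(seq_along(config$block_sizes), config$block_sizes)
}

#' Simulate SIS engagement ground truth and its observable stream
#'
#' Discrete-day stochastic adoption: each uncommitted user active in the
#' trailing window becomes engaged with probability `alpha_t E_{t-1} /
#' N_{t-1}`; engaged users disengage with a per-day hazard once past the
#' minimum engagement duration. Because the observational definition of
#' engagement (a category post within `(t - tau, t]`) cannot register spells
#' shorter than `tau` days, engagement spells last at least `tau` days and
#' the post-minimum hazard is compensated to `beta / (1 - beta (tau - 1))`
#' so that the aggregate per-day disengagement rate equals the configured
#' `beta`. Category posts are then laid down so that the windowed
#' reconstruction of the latent state from the emitted stream is *exact*
#' (one post at spell start, refreshed every `tau` days, last post exactly
#' `tau - 1` days before the spell ends).
#'
#' The returned stream contains the category posts plus the base activity
#' originals (no retweet cascades): the cascade layer is added by
#' [simulate_cascades()], whose retweets of category posts intentionally
#' spread observable engagement beyond this SIS ground truth.
#'
#' @param config A `synth_config`.
#' @return An `engagement_truth` list: `states` (users x days logical
#'   matrix of the latent = observable engagement), `events` (the
#'   engagement stream tibble), `alpha`, `beta`, `config`.
#' @export
simulate_engagement <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_users
  days <- config$days
  tau <- config$tau
  users <- .user_ids(n)
  blocks <- .user_blocks(config)
  withr::with_seed(config$seed, {
    base_post <- matrix(runif(n * days) < config$tweet_rate, n, days)
    lat <- matrix(FALSE, n, days, dimnames = list(users, NULL))
    age <- rep(-1L, n)
    n_seed <- max(1L, round(config$init_engaged * n))
    s0 <- sample.int(n, n_seed)
    lat[s0, 1] <- TRUE
    age[s0] <- 0L
    basewin <- matrix(FALSE, n, days)
    for (t in seq_len(days)) {
      lo <- max(1L, t - tau + 1L)
      basewin[, t] <- rowSums(base_post[, lo:t, drop = FALSE]) > 0
    }
    h <- config$beta / (1 - config$beta * (tau - 1))
    for (t in 2:days) {
      active_prev <- basewin[, t - 1] | lat[, t - 1]
      E <- sum(lat[, t - 1])
      N <- sum(active_prev)
      lat[, t] <- lat[, t - 1]
      if (E > 0 && N > 0) {
        u <- which(active_prev & !lat[, t - 1])
        p_eng <- min(1, config$alpha[t] * E / N)
        eng <- u[runif(length(u)) < p_eng]
        lat[eng, t] <- TRUE
        elig <- which(lat[, t - 1] & age >= tau - 1)
        dis <- elig[runif(length(elig)) < h[t]]
        lat[dis, t] <- FALSE
        age[eng] <- 0L
        stay <- setdiff(which(lat[, t - 1]), dis)
        age[stay] <- age[stay] + 1L
        age[dis] <- -1L
      }
    }
    # exact emission: windowed reconstruction of `lat` from posts is the
    # identity (posts at spell start, every tau days, final at end - tau + 1)
    cat_post <- matrix(FALSE, n, days)
    for (u in seq_len(n)) {
      r <- rle(lat[u, ])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts[k]
        b <- ends[k]
        last <- if (b == days) b else b - tau + 1L
        ps <- seq(a, max(a, last), by = tau)
        if (last >= a) ps <- unique(c(ps, last))
        cat_post[u, ps[ps >= a]] <- TRUE
      }
    }
    ev_base <- which(base_post, arr.ind = TRUE)
    ev_cat <- which(cat_post, arr.ind = TRUE)
    n_b <- nrow(ev_base)
    n_c <- nrow(ev_cat)
    urls_b <- ifelse(
      runif(n_b) < config$media_share,
      sample(config$media_urls, n_b, replace = TRUE), NA_character_
    )
    urls_c <- sample(config$category_urls, n_c, replace = TRUE)
    tags_b <- .sample_hashtags(config, blocks[ev_base[, 1]])
    tags_c <- .sample_hashtags(config, blocks[ev_cat[, 1]])
    events <- tibble(
      tweet_id = sprintf("t%08d", seq_len(n_b + n_c)),
      user_id = users[c(ev_base[, 1], ev_cat[, 1])],
      day = as.integer(c(ev_base[, 2], ev_cat[, 2])),
      is_retweet = FALSE,
      root_tweet_id = sprintf("t%08d", seq_len(n_b + n_c)),
      urls = lapply(c(urls_b, urls_c), function(u) u[!is.na(u)]),
      hashtags = as.list(c(tags_b, tags_c))
    )
    events <- events[order(events$day, events$tweet_id), , drop = FALSE]
    structure(
      list(states = lat, events = events, alpha = config$alpha,
           beta = config$beta, config = config),
      class = "engagement_truth"
    )
  })
}

.sample_hashtags <- function(config, blocks) {
  vocab <- config$hashtags
  vapply(blocks, function(k) {
    w <- config$hashtag_bias[k, ]
    sample(vocab, 1, prob = w / sum(w))
  }, character(1))
}

.mixing_for <- function(config, content, day) {
  mx <- config$mixing
  if (!is.null(config$period_breaks) && !is.null(config$period_mixing)) {
    pd <- findInterval(day, c(-Inf, sort(config$period_breaks))) # 1-based period
    if (pd <= length(config$period_mixing)) mx <- config$period_mixing[[pd]]
  }
  if (content == "category" && !is.null(config$category_mixing)) {
    mx <- config$category_mixing
  } else if (content == "media" && !is.null(config$media_mixing)) {
    mx <- config$media_mixing
  }
  mx
}

#' Simulate a full cascade event stream
#'
#' Lays retweet cascades over the root tweets of an engagement simulation
#' (or over planted per-block category posting when
#' `block_category_rate` is configured): every original draws a geometric
#' head size, head users are sampled from blocks through the (content- and
#' period-specific) mixing matrix and retweet the root on its day.
#' Retweets inherit the root's URLs and hashtags. The output is sorted and
#' format-valid for [read_events()]/[as_tweet_events()].
#'
#' @param config A `synth_config`.
#' @param engagement Optional `engagement_truth` from
#'   [simulate_engagement()] (computed from `config` when absent and no
#'   planted category rate is configured).
#' @return An event tibble (originals plus retweets) with attribute
#'   `blocks` giving the planted block of every user.
#' @export
simulate_cascades <- function(config, engagement = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_users
  users <- .user_ids(n)
  blocks <- .user_blocks(config)
  users_by_block <- split(seq_len(n), blocks)

  if (is.null(config$block_category_rate)) {
    if (is.null(engagement)) engagement <- simulate_engagement(config)
    roots <- engagement$events
  } else {
    roots <- withr::with_seed(config$seed, {
      base <- which(matrix(runif(n * config$days) < config$tweet_rate,
                           n, config$days), arr.ind = TRUE)
      rate <- rep_len(config$block_category_rate, length(config$block_sizes))
      catm <- which(matrix(runif(n * config$days) < rate[blocks],
                           n, config$days), arr.ind = TRUE)
      n_b <- nrow(base)
      n_c <- nrow(catm)
      urls_b <- ifelse(runif(n_b) < config$media_share,
                       sample(config$media_urls, n_b, replace = TRUE),
                       NA_character_)
      urls_c <- sample(config$category_urls, n_c, replace = TRUE)
      tibble(
        tweet_id = sprintf("t%08d", seq_len(n_b + n_c)),
        user_id = users[c(base[, 1], catm[, 1])],
        day = as.integer(c(base[, 2], catm[, 2])),
        is_retweet = FALSE,
        root_tweet_id = sprintf("t%08d", seq_len(n_b + n_c)),
        urls = lapply(c(urls_b, urls_c), function(u) u[!is.na(u)]),
        hashtags = as.list(.sample_hashtags(
          config, blocks[c(base[, 1], catm[, 1])]
        ))
      )
    })
  }

  withr::with_seed(config$seed + 1L, {
    n_roots <- nrow(roots)
    p_geom <- 1 / (config$head_size_mean + 1)
    sizes <- pmin(rgeom(n_roots, p_geom), n - 1L)
    has_casc <- which(sizes > 0)
    is_cat <- vapply(roots$urls, function(u) any(u %in% config$category_urls),
                     logical(1))
    slots <- tibble(
      root = rep(has_casc, sizes[has_casc])
    )
    if (nrow(slots) > 0) {
      poster_idx <- match(roots$user_id, users)
      pb <- poster_idx[slots$root]
      content <- ifelse(is_cat[slots$root], "category", "media")
      day <- roots$day[slots$root]
      # block of each retweeter, drawn through the applicable mixing row
      nb <- length(config$block_sizes)
      slots$block <- NA_integer_
      key <- paste(blocks[pb], content, day)
      for (kk in unique(key)) {
        idx <- which(key == kk)
        parts <- strsplit(kk, " ", fixed = TRUE)[[1]]
        mx <- .mixing_for(config, parts[2], as.integer(parts[3]))
        row <- mx[as.integer(parts[1]), ]
        slots$block[idx] <- sample.int(nb, length(idx), replace = TRUE,
                                       prob = row)
      }
      slots$user <- NA_integer_
      for (b in unique(slots$block)) {
        idx <- which(slots$block == b)
        pool <- users_by_block[[b]]
        slots$user[idx] <- pool[sample.int(length(pool), length(idx),
                                           replace = TRUE)]
      }
      # drop self-retweets and duplicate retweeters of the same root
      keep <- slots$user != pb & !duplicated(paste(slots$root, slots$user))
      slots <- slots[keep, , drop = FALSE]
    }
    if (nrow(slots) > 0) {
      rts <- tibble(
        tweet_id = sprintf("r%08d", seq_len(nrow(slots))),
        user_id = users[slots$user],
        day = roots$day[slots$root],
        is_retweet = TRUE,
        root_tweet_id = roots$tweet_id[slots$root],
        urls = roots$urls[slots$root],
        hashtags = roots$hashtags[slots$root]
      )
      out <- bind_rows(roots, rts)
    } else {
      out <- roots
    }
    out <- out[order(out$day, out$tweet_id), , drop = FALSE]
    attr(out, "blocks") <- setNames(blocks, users)
    out
  })
}

#' Write the suite of micro-fixtures with a manifest
#'
#' Writes the small named fixtures used across the documentation and tests
#' (two-node cycle, star cascade, the two-hyper-edge transition example, two
#' weakly joined cliques, a planted four-block stream and an
#' echo-chamber-versus-spreader pair), each as line-delimited JSON, plus a
#' `manifest.json` recording per-fixture expected values that the test
#' oracles re-derive. Byte-identical output under the same seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the generated fixtures.
#' @return The manifest, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(paste0("cannot create directory ", dir))
  }
  ev <- function(id, user, day, rt = FALSE, root = id, urls = character(),
                 tags = character()) {
    tibble(tweet_id = id, user_id = user, day = as.integer(day),
           is_retweet = rt, root_tweet_id = root, urls = list(urls),
           hashtags = list(tags))
  }
  fixtures <- list()
  fixtures$two_cycle <- bind_rows(
    ev("t1", "A", 1), ev("r1", "B", 1, TRUE, "t1"),
    ev("t2", "B", 2), ev("r2", "A", 2, TRUE, "t2")
  )
  fixtures$star_cascade <- bind_rows(
    ev("t1", "A", 1),
    ev("r1", "B", 1, TRUE, "t1"), ev("r2", "C", 1, TRUE, "t1"),
    ev("r3", "D", 1, TRUE, "t1")
  )
  fixtures$two_hyperedge <- bind_rows(
    ev("t1", "A", 1), ev("r1", "B", 1, TRUE, "t1"),
    ev("r2", "C", 1, TRUE, "t1"),
    ev("t2", "A", 2), ev("r3", "B", 2, TRUE, "t2"),
    # close the walk so the chain has no absorbing sink
    ev("t3", "B", 3), ev("r4", "A", 3, TRUE, "t3"),
    ev("t4", "C", 3), ev("r5", "A", 3, TRUE, "t4")
  )
  clique <- function(us, t0, prefix) {
    rows <- list()
    k <- 0
    for (u in us) {
      k <- k + 1
      id <- paste0(prefix, k)
      rows[[length(rows) + 1]] <- ev(id, u, t0 + k)
      for (v in setdiff(us, u)) {
        rows[[length(rows) + 1]] <-
          ev(paste0(id, "_", v), v, t0 + k, TRUE, id)
      }
    }
    bind_rows(rows)
  }
  fixtures$two_clique <- bind_rows(
    clique(paste0("a", 1:5), 0, "ta"),
    clique(paste0("b", 1:5), 10, "tb"),
    ev("tx", "a1", 20), ev("tx_rt", "b1", 20, TRUE, "tx")
  )
  cfg4 <- synth_config(
    n_users = 40, block_sizes = rep(10L, 4), assortativity = 0.9,
    tweet_rate = 0.3, days = 30, alpha = 0, init_engaged = 0.05,
    seed = seed
  )
  fixtures$planted_4block <- simulate_cascades(cfg4)
  cfg_echo <- echo_chamber_config(n_per_block = 20, days = 40, seed = seed)
  fixtures$echo_pair <- simulate_cascades(cfg_echo)

  manifest <- list(
    seed = seed,
    fixtures = list(
      two_cycle = list(file = "two_cycle.jsonl", n_cascades = 2,
                       stationary = c(A = 0.5, B = 0.5), damping = 1),
      star_cascade = list(file = "star_cascade.jsonl", n_cascades = 1,
                          head_size = 3),
      two_hyperedge = list(file = "two_hyperedge.jsonl",
                           T_A_B = 0.75, T_A_C = 0.25),
      two_clique = list(file = "two_clique.jsonl", n_communities = 2),
      planted_4block = list(file = "planted_4block.jsonl", n_blocks = 4,
                            provenance = "synthetic"),
      echo_pair = list(file = "echo_pair.jsonl",
                       echo_block = 1, spreader_block = 2,
                       provenance = "synthetic")
    )
  )
  for (nm in names(fixtures)) {
    write_events(fixtures[[nm]], file.path(dir, paste0(nm, ".jsonl")))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Configuration of the echo-chamber-versus-spreader fixture
#'
#' Three equal blocks with prescribed content geography: block 1 (the echo
#' chamber) posts the tagged category heavily and its category cascades
#' recirculate internally while it also absorbs category content produced
#' elsewhere; block 2 (the spreader) adopts rarely but its category
#' cascades are re-broadcast outward; block 3 is a mixing public. Media
#' cascades invert the geography (the echo block diffuses media outward,
#' the spreader keeps media internal), so the escape-probability ordering
#' flips between the category- and media-restricted hyper-graphs.
#'
#' @param n_per_block Users per block.
#' @param days Stream length in days.
#' @param seed Integer seed.
#' @return A `synth_config`.
#' @export
echo_chamber_config <- function(n_per_block = 30, days = 60, seed = 1L) {
  synth_config(
    n_users = 3 * n_per_block,
    block_sizes = rep(n_per_block, 3),
    mixing = matrix(c(
      0.70, 0.15, 0.15,
      0.15, 0.70, 0.15,
      0.15, 0.15, 0.70
    ), 3, 3, byrow = TRUE),
    category_mixing = matrix(c(
      0.94, 0.02, 0.04,  # echo block: category recirculates inside
      0.05, 0.10, 0.85,  # spreader: category cascades leave the block
      0.60, 0.10, 0.30   # public: category it posts is absorbed by the echo
    ), 3, 3, byrow = TRUE),
    media_mixing = matrix(c(
      0.20, 0.20, 0.60,  # echo block broadcasts media outward
      0.10, 0.80, 0.10,  # spreader keeps media internal
      0.30, 0.20, 0.50
    ), 3, 3, byrow = TRUE),
    block_category_rate = c(0.12, 0.02, 0.05),
    tweet_rate = 0.25, days = days, seed = seed
  )
}
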