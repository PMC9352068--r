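#' @name engagement
#' @title Sliding-window engagement dynamics
#'
#' @description
#' A user is *engaged* at day `t` when they posted or reshared a link of the
#' tracked content category within the trailing window `(t - tau, t]`; they
#' are *active* when they posted anything in the same window. Treating
#' engaged users as the infectious compartment of an SIS process, the daily
#' inflow and outflow of the engaged set identify a time-varying contact rate
#' `alpha_t`, a loss-of-interest rate `beta_t` and their ratio `R_t`, the
#' reproduction number of content adoption:
#' \deqn{dE^+_t = \alpha_t E_t (N_t - E_t) / N_t, \quad dE^-_t = \beta_t E_t,
#'   \quad R_t = \alpha_t/\beta_t.}
#' Rates are inverted with the predecessor convention (exposure at `t - 1`
#' drives transitions observed at `t`).
NULL

# days x users logical matrix: any event in the half-open window (t - tau, t]
.window_state <- function(user_days, users, days, tau) {
  n_u <- length(users)
  n_d <- length(days)
  act <- matrix(FALSE, n_u, n_d, dimnames = list(users, NULL))
  if (nrow(user_days)) {
    di <- match(user_days$day, days)
    ui <- match(user_days$user_id, users)
    keep <- !is.na(di) & !is.na(ui)
    act[cbind(ui[keep], di[keep])] <- TRUE
  }
  win <- matrix(FALSE, n_u, n_d, dimnames = list(users, NULL))
  for (t in seq_len(n_d)) {
    lo <- max(1L, t - tau + 1L)
    win[, t] <- rowSums(act[, lo:t, drop = FALSE]) > 0
  }
  win
}

.state_matrices <- function(events, category_events, tau, days = NULL) {
  stopifnot(tau >= 1)
  all_days <- c(events$day, category_events$day)
  if (length(all_days) == 0) {
    return(list(days = integer(), engaged = matrix(FALSE, 0, 0),
                active = matrix(FALSE, 0, 0)))
  }
  if (is.null(days)) days <- seq(min(all_days), max(all_days))
  users <- sort(unique(c(events$user_id, category_events$user_id)))
  ad <- distinct(bind_rows(
    events[c("user_id", "day")], category_events[c("user_id", "day")]
  ))
  cd <- distinct(category_events[c("user_id", "day")])
  list(
    days = as.integer(days),
    engaged = .window_state(cd, users, days, tau),
    active = .window_state(ad, users, days, tau)
  )
}

#' Count engaged and active users per day
#'
#' `E_t` counts users with at least one category event in `(t - tau, t]`;
#' `N_t` counts users with at least one event of any kind in the same
#' window, so `E_t <= N_t` whenever `category_events` is a subset of
#' `events`. Days before the stream start yield zero counts.
#'
#' @param events Event tibble (the full activity stream).
#' @param category_events Subset of `events` carrying the tracked category,
#'   e.g. from [classify_events()].
#' @param tau Window length in days (default 3).
#' @param days Optional integer vector of days to evaluate (defaults to the
#'   full stream range).
#' @return A tibble with columns `day`, `E`, `N`.
#' @export
engagement_states <- function(events, category_events, tau = 3, days = NULL) {
  sm <- .state_matrices(events, category_events, tau, days)
  tibble(day = sm$days, E = as.integer(colSums(sm$engaged)),
         N = as.integer(colSums(sm$active)))
}

#' Daily inflow and outflow of the engaged set
#'
#' Counts per-user transitions between consecutive days: `dE_plus` is the
#' number of uncommitted-to-engaged transitions at `t`, `dE_minus` the
#' engaged-to-uncommitted ones. The conservation identity
#' `E_t - E_{t-1} = dE_plus_t - dE_minus_t` holds exactly.
#'
#' @param engaged A users x days logical matrix of engagement states.
#' @return A tibble with columns `day_index`, `dE_plus`, `dE_minus` (first
#'   day has zero flows by convention).
#' @export
engagement_flows <- function(engaged) {
  n_d <- ncol(engaged)
  dE_plus <- integer(n_d)
  dE_minus <- integer(n_d)
  if (n_d >= 2) {
    for (t in 2:n_d) {
      dE_plus[t] <- sum(engaged[, t] & !engaged[, t - 1])
      dE_minus[t] <- sum(!engaged[, t] & engaged[, t - 1])
    }
  }
  tibble(day_index = seq_len(n_d), dE_plus = dE_plus, dE_minus = dE_minus)
}

#' Invert the SIS balance equations for daily rates
#'
#' Fills `alpha`, `beta` and `R` from daily states and flows using the
#' predecessor convention:
#' `alpha_t = dE_plus_t N_{t-1} / (E_{t-1} (N_{t-1} - E_{t-1}))` and
#' `beta_t = dE_minus_t / E_{t-1}`. Days violating the preconditions
#' (`E_{t-1} = 0` for `beta`; additionally `E_{t-1} = N_{t-1}` for `alpha`)
#' are returned as `NA`, never as fabricated zeros; `R` is `NA` wherever
#' `beta` is undefined or zero.
#'
#' @param series A tibble with columns `day`, `E`, `N`, `dE_plus`,
#'   `dE_minus`.
#' @return The same tibble with `alpha`, `beta`, `R` columns filled.
#' @export
estimate_rates <- function(series) {
  n <- nrow(series)
  alpha <- rep(NA_real_, n)
  beta <- rep(NA_real_, n)
  if (n >= 2) {
    Ep <- series$E[-n]
    Np <- series$N[-n]
    idx <- 2:n
    ok_b <- Ep > 0
    beta[idx][ok_b] <- series$dE_minus[idx][ok_b] / Ep[ok_b]
    ok_a <- Ep > 0 & Ep < Np
    alpha[idx][ok_a] <- series$dE_plus[idx][ok_a] * Np[ok_a] /
      (Ep[ok_a] * (Np[ok_a] - Ep[ok_a]))
  }
  series$alpha <- alpha
  series$beta <- beta
  series$R <- reproduction_number(alpha, beta)
  series
}

#' Reproduction number of content adoption
#'
#' The ratio `R_t = alpha_t / beta_t`; above 1 the engaged population grows
#' by contact. Undefined rates propagate and `beta = 0` yields `NA`.
#'
#' @param alpha,beta Numeric vectors of daily rates.
#' @return Numeric vector of the same length.
#' @export
reproduction_number <- function(alpha, beta) {
  r <- alpha / beta
  r[!is.na(beta) & beta == 0] <- NA_real_
  r
}

#' Full daily engagement series for one content category
#'
#' One call that chains [engagement_states()], [engagement_flows()] and
#' [estimate_rates()] into the tidy per-day table used by the rest of the
#' pipeline.
#'
#' @inheritParams engagement_states
#' @return An `engagement_series` tibble with columns `day`, `E`, `N`,
#'   `dE_plus`, `dE_minus`, `alpha`, `beta`, `R` and attribute `tau`.
#' @export
engagement_series <- function(events, category_events, tau = 3, days = NULL) {
  sm <- .state_matrices(events, category_events, tau, days)
  fl <- engagement_flows(sm$engaged)
  ser <- tibble(
    day = sm$days,
    E = as.integer(colSums(sm$engaged)),
    N = as.integer(colSums(sm$active)),
    dE_plus = fl$dE_plus, dE_minus = fl$dE_minus
  )
  ser <- estimate_rates(ser)
  attr(ser, "tau") <- tau
  class(ser) <- c("engagement_series", class(ser))
  ser
}

#' Detect engagement events as peaks of the reproduction number
#'
#' Short gaps in the `R` series (undefined rates on degenerate days) are
#' linearly interpolated up to `max_gap` days, the series is smoothed with a
#' centered rolling median, and local maxima exceeding a quantile threshold
#' are reported. When two peaks fall closer than `min_separation` days the
#' higher one is kept. Deterministic given its configuration.
#'
#' @param series An `engagement_series` (or any tibble with `day` and `R`).
#' @param smooth_width Width (days) of the rolling median (default 7).
#' @param threshold_quantile Quantile of the smoothed series a peak must
#'   exceed (default 0.9).
#' @param min_separation Minimum distance between reported peaks, in days.
#' @param max_gap Longest run of undefined days to interpolate across.
#' @return A tibble with columns `day`, `R_smooth`, sorted by day; empty when
#'   the series has no defined values.
#' @export
detect_engagement_events <- function(series, smooth_width = 7,
                                     threshold_quantile = 0.9,
                                     min_separation = 7, max_gap = 2) {
  x <- series$R
  if (all(is.na(x))) return(tibble(day = integer(), R_smooth = double()))
  x <- zoo::na.approx(x, na.rm = FALSE, maxgap = max_gap)
  # full windows only: medians over truncated edge windows are dominated by
  # the stream's startup/shutdown transients and produce spurious peaks
  s <- zoo::rollapply(zoo::zoo(x), width = smooth_width,
                      FUN = function(z) {
                        if (all(is.na(z))) NA_real_ else median(z, na.rm = TRUE)
                      },
                      align = "center", fill = NA)
  s <- as.numeric(s)
  if (all(is.na(s))) return(tibble(day = integer(), R_smooth = double()))
  thr <- quantile(s, threshold_quantile, na.rm = TRUE, names = FALSE)
  n <- length(s)
  is_peak <- vapply(seq_len(n), function(t) {
    if (is.na(s[t]) || s[t] <= thr) return(FALSE)
    left <- if (t > 1) s[t - 1] else -Inf
    right <- if (t < n) s[t + 1] else -Inf
    isTRUE(s[t] >= left) && isTRUE(s[t] >= right)
  }, logical(1))
  cand <- which(is_peak)
  if (length(cand) == 0) return(tibble(day = integer(), R_smooth = double()))
  # rolling medians flatten sharp maxima into plateaus of equal value:
  # collapse each run of consecutive equal-valued candidates to its center
  grp <- cumsum(c(1, diff(cand) != 1 | s[cand[-1]] != s[cand[-length(cand)]]))
  cand <- vapply(split(cand, grp),
                 function(ix) ix[ceiling(length(ix) / 2)], numeric(1))
  cand <- cand[order(-s[cand], cand)]
  kept <- integer()
  for (t in cand) {
    if (all(abs(t - kept) >= min_separation)) kept <- c(kept, t)
  }
  kept <- sort(kept)
  tibble(day = series$day[kept], R_smooth = s[kept])
}
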