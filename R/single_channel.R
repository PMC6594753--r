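#' Zero-phase Gaussian smoothing of a current trace
#'
#' Smooths the current with a Gaussian kernel whose -3 dB corner frequency is
#' `corner` Hz (kernel sigma = sqrt(ln 2) / (2 * pi * corner)); DC gain is 1
#' and edges are handled by reflection, so a constant trace passes unchanged.
#'
#' @param data Data frame with uniformly sampled time and current columns.
#' @param corner Corner (-3 dB) frequency, Hz; must be below the Nyquist
#'   frequency.
#' @param time,current Column names (tidy-eval); defaults `time_s`, `current`.
#'
#' @return `data` with the current column replaced by its filtered version.
#' @export
gaussian_filter <- function(data, corner, time = time_s, current = current) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ current }})
  dt <- median(diff(t))
  fs <- 1 / dt
  if (corner >= fs / 2) abort("corner frequency must be below Nyquist (sampling_rate / 2)")
  sigma_s <- sqrt(log(2)) / (2 * pi * corner)
  sigma_n <- sigma_s / dt
  half <- max(1L, ceiling(4 * sigma_n))
  kern <- exp(-0.5 * ((-half):half / sigma_n)^2)
  kern <- kern / sum(kern)
  ypad <- c(rev(y[seq_len(half)]), y, rev(y[seq.int(length(y) - half + 1, length(y))]))
  smoothed <- stats::filter(ypad, kern, sides = 2)
  out <- data
  out[[rlang::as_name(rlang::enquo(current))]] <-
    as.numeric(smoothed[(half + 1):(half + length(y))])
  out
}

new_event_list <- function(level, duration_s, dead_time, n_channels) {
  structure(tibble(level = as.integer(level), duration_s = duration_s),
            class = c("event_list", "tbl_df", "tbl", "data.frame"),
            dead_time = dead_time, n_channels = as.integer(n_channels))
}

# merge events shorter than the dead time into the preceding event
# (concatenation), then collapse adjacent equal levels.
apply_dead_time <- function(level, duration, dead_time) {
  stopifnot(length(level) == length(duration))
  # drop leading sub-dead-time runs into the first resolvable event
  first_ok <- which(duration >= dead_time)[1]
  if (is.na(first_ok)) {
    return(list(level = level[1], duration = sum(duration)))
  }
  if (first_ok > 1) {
    lead <- sum(duration[seq_len(first_ok - 1)])
    level <- level[first_ok:length(level)]
    duration <- duration[first_ok:length(duration)]
    duration[1] <- duration[1] + lead
  }
  out_lv <- integer(length(level))
  out_du <- numeric(length(level))
  k <- 1L
  out_lv[1] <- level[1]
  out_du[1] <- duration[1]
  for (i in seq_along(level)[-1]) {
    if (duration[i] < dead_time || level[i] == out_lv[k]) {
      out_du[k] <- out_du[k] + duration[i]
    } else {
      k <- k + 1L
      out_lv[k] <- level[i]
      out_du[k] <- duration[i]
    }
  }
  list(level = out_lv[seq_len(k)], duration = out_du[seq_len(k)])
}

#' Half-amplitude idealization of a current trace
#'
#' Assigns each sample the number of half-amplitude thresholds
#' `(k - 1/2) * unitary_current`, `k = 1..n_channels`, that it exceeds, then
#' collapses the level sequence into dwell events. Events shorter than the
#' dead time are merged into the preceding event (concatenation), emulating
#' the resolution limit of the filtered recording.
#'
#' @param data Data frame with uniformly sampled time and current columns.
#' @param unitary_current Single-channel current amplitude (same units as the
#'   current column).
#' @param n_channels Number of active channels in the patch.
#' @param dead_time Shortest resolvable dwell (s); default 6 ms.
#' @param time,current Column names (tidy-eval); defaults `time_s`, `current`.
#'
#' @return An `event_list` tibble with columns `level` and `duration_s`, and
#'   attributes `dead_time`, `n_channels`.
#' @export
idealize <- function(data, unitary_current, n_channels,
                     dead_time = .const$dead_time,
                     time = time_s, current = current) {
  if (unitary_current <= 0) abort("`unitary_current` must be positive")
  if (n_channels < 1) abort("`n_channels` must be >= 1")
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ current }})
  dt <- median(diff(t))
  lev <- pmin(pmax(floor(y / unitary_current + 0.5), 0), n_channels)
  r <- rle(as.integer(lev))
  merged <- apply_dead_time(r$values, r$lengths * dt, dead_time)
  new_event_list(merged$level, merged$duration, dead_time, n_channels)
}

check_events <- function(events) {
  if (!inherits(events, "event_list")) {
    abort("`events` must be an `event_list` (see `idealize()` / `sim_cob_events()`)")
  }
  if (nrow(events) == 0) abort("empty event list")
  events
}

#' Open probability from an event list
#'
#' Time-averaged fraction of open channels:
#' `sum(level * duration) / (n_channels * sum(duration))`.
#'
#' @param events An `event_list`.
#' @return Probability in `[0, 1]`.
#' @export
open_probability <- function(events) {
  check_events(events)
  nch <- attr(events, "n_channels")
  sum(events$level * events$duration_s) / (nch * sum(events$duration_s))
}

#' Open probability over sequential time windows (stability plot)
#'
#' Splits the record into consecutive non-overlapping windows (46 s by
#' default) and evaluates the open probability in each; a partial final
#' window is dropped. Sudden switches between low- and high-activity gating
#' show up as steps in this series.
#'
#' @param events An `event_list`.
#' @param window Window length (s).
#' @return A tibble with `window` (index), `t_start`, `t_end`, `p_open`.
#' @export
stability_windows <- function(events, window = 46) {
  check_events(events)
  nch <- attr(events, "n_channels")
  total <- sum(events$duration_s)
  n_win <- floor(total / window)
  if (n_win < 1) abort(sprintf("record (%.1f s) is shorter than one %g-s window",
                               total, window))
  # cumulative open-time integral at event boundaries -> piecewise linear
  bounds <- c(0, cumsum(events$duration_s))
  open_int <- c(0, cumsum(events$level * events$duration_s))
  I <- function(x) approx(bounds, open_int, xout = x, rule = 2)$y
  edges <- seq(0, n_win * window, by = window)
  p_open <- diff(I(edges)) / (nch * window)
  tibble(
    window = seq_len(n_win),
    t_start = edges[-length(edges)],
    t_end = edges[-1],
    p_open = p_open
  )
}

# stationary distribution of the C-O-B scheme (states closed, open, blocked)
cob_stationary <- function(r_co, r_oc, r_ob, r_bo) {
  w <- c(C = r_oc / r_co, O = 1, B = r_ob / r_bo)
  w / sum(w)
}

#' Mean burst metrics and stationary open probability of a C-O-B scheme
#'
#' From the four microscopic rates of the closed-open-blocked scheme:
#' mean burst duration `tau_b = (1/r_OC) * (1 + r_OB/r_BO)` (open time
#' extended by flickery closures), mean interburst duration
#' `tau_ib = 1/r_CO`, opening rate `1/tau_ib`, closing rate `1/tau_b`, and
#' the stationary open probability of the three-state scheme.
#'
#' @param r_co,r_oc,r_ob,r_bo Transition rates (s^-1): closed->open,
#'   open->closed, open->blocked, blocked->open.
#' @return A one-row tibble with `tau_b`, `tau_ib`, `opening_rate`,
#'   `closing_rate`, `p_open`.
#' @export
#' @examples
#' burst_summary(r_co = 0.2, r_oc = 1, r_ob = 18, r_bo = 110)
burst_summary <- function(r_co, r_oc, r_ob, r_bo) {
  if (any(c(r_co, r_oc, r_bo) <= 0) || r_ob < 0) {
    abort("rates must be positive (r_ob may be zero)")
  }
  tau_b <- (1 / r_oc) * (1 + r_ob / r_bo)
  tau_ib <- 1 / r_co
  tibble(tau_b = tau_b, tau_ib = tau_ib,
         opening_rate = 1 / tau_ib, closing_rate = 1 / tau_b,
         p_open = unname(cob_stationary(r_co, r_oc, r_ob, r_bo)["O"]))
}

#' Burst durations from an event list
#'
#' Groups open dwells separated by shut dwells shorter than `t_crit` into
#' bursts and returns each burst's total duration (openings plus bridged
#' flickery closures). Only meaningful for single-channel records.
#'
#' @param events An `event_list` with `n_channels == 1`.
#' @param t_crit Critical shut duration (s) separating intraburst flickers
#'   from interburst closures.
#' @return Numeric vector of burst durations (s).
#' @export
burst_durations <- function(events, t_crit) {
  check_events(events)
  if (attr(events, "n_channels") != 1) abort("burst analysis needs a single-channel record")
  lv <- events$level
  du <- events$duration_s
  bursts <- numeric(0)
  cur <- 0
  in_burst <- FALSE
  for (i in seq_along(lv)) {
    if (lv[i] >= 1) {
      cur <- cur + du[i]
      in_burst <- TRUE
    } else if (in_burst) {
      if (du[i] < t_crit) {
        cur <- cur + du[i] # flicker bridged into the burst
      } else {
        bursts <- c(bursts, cur)
        cur <- 0
        in_burst <- FALSE
      }
    }
  }
  if (in_burst) bursts <- c(bursts, cur)
  bursts
}

#' Maximum-likelihood C-O-B rates from a single-channel event list
#'
#' Fits the closed-open-blocked scheme to the dwell times of an idealized
#' single-channel record by maximizing a dead-time-corrected likelihood.
#' Open dwells are modelled as a left-truncated exponential whose effective
#' rate `r_OC * exp(-r_CO * td) + r_OB * exp(-r_BO * td)` counts only
#' transitions into shut dwells long enough (>= dead time `td`) to be
#' detected — a first-order missed-event correction, since unseen brief
#' closures bridge consecutive openings. Shut dwells are modelled as a
#' left-truncated two-exponential mixture with component rates `r_CO`, `r_BO`
#' and entry weights `r_OC : r_OB`. This is a deliberate simplification of
#' exact missed-event likelihoods; see the methods vignette.
#'
#' The first and last dwells are censored and excluded.
#'
#' @param events An `event_list` from a single-channel record
#'   (`n_channels == 1`), dead-time concatenated.
#' @return An object of class `cob_fit`: `r_co`, `r_oc`, `r_ob`, `r_bo`
#'   (s^-1), `loglik`, `n_open`, `n_shut`, `converged`.
#' @export
fit_cob <- function(events) {
  check_events(events)
  if (attr(events, "n_channels") != 1) {
    abort("C-O-B rate fitting is implemented for single-channel records only")
  }
  td <- attr(events, "dead_time")
  lv <- events$level
  du <- events$duration_s
  if (length(lv) > 2) {
    lv <- lv[-c(1, length(lv))]
    du <- du[-c(1, length(du))]
  }
  t_open <- du[lv == 1]
  t_shut <- du[lv == 0]
  n_ev <- length(t_open) + length(t_shut)
  if (n_ev < 50) abort("too few events (< 50) for a C-O-B fit")
  if (n_ev < 200) warn("fewer than 200 events; C-O-B rate estimates will be imprecise")

  negll <- function(lr) {
    r <- exp(lr) # r_co, r_oc, r_ob, r_bo
    lam_eff <- r[2] * exp(-r[1] * td) + r[3] * exp(-r[4] * td)
    p_c <- r[2] / (r[2] + r[3])
    p_b <- r[3] / (r[2] + r[3])
    ll_open <- sum(log(lam_eff) - lam_eff * (t_open - td))
    dens <- p_c * r[1] * exp(-r[1] * t_shut) + p_b * r[4] * exp(-r[4] * t_shut)
    surv_td <- p_c * exp(-r[1] * td) + p_b * exp(-r[4] * td)
    ll_shut <- sum(log(dens)) - length(t_shut) * log(surv_td)
    -(ll_open + ll_shut)
  }

  # moment-based starting values: split shut dwells into brief and long
  split <- max(5 * td, 3 * td)
  brief <- t_shut[t_shut < split]
  long <- t_shut[t_shut >= split]
  r_bo0 <- if (length(brief) > 5) 1 / max(mean(brief) - td, td / 2) else 1 / (2 * td)
  r_co0 <- if (length(long) > 5) 1 / mean(long) else 1 / max(mean(t_shut), td)
  lam0 <- 1 / max(mean(t_open) - td, td / 2)
  frac_brief <- max(length(brief) / max(length(t_shut), 1), 0.02)
  r_ob0 <- max(lam0 * frac_brief, 1e-3)
  r_oc0 <- max(lam0 - r_ob0, 1e-3)

  start <- log(c(r_co0, r_oc0, r_ob0, r_bo0))
  o <- optim(start, negll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-10))
  o <- optim(o$par, negll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-10))
  r <- exp(o$par)
  structure(
    list(r_co = r[1], r_oc = r[2], r_ob = r[3], r_bo = r[4],
         loglik = -o$value, n_open = length(t_open), n_shut = length(t_shut),
         converged = o$convergence == 0),
    class = "cob_fit"
  )
}

#' @export
print.cob_fit <- function(x, ...) {
  cat(sprintf("<cob_fit> r_CO = %.4g, r_OC = %.4g, r_OB = %.4g, r_BO = %.4g s^-1 (%d open / %d shut dwells)%s\n",
              x$r_co, x$r_oc, x$r_ob, x$r_bo, x$n_open, x$n_shut,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Gating summary from a fitted C-O-B scheme
#'
#' Convenience wrapper turning a [fit_cob()] result into burst metrics via
#' [burst_summary()].
#'
#' @param fit A `cob_fit`.
#' @return The one-row tibble of [burst_summary()].
#' @export
gating_summary <- function(fit) {
  if (!inherits(fit, "cob_fit")) abort("`fit` must be a cob_fit")
  burst_summary(fit$r_co, fit$r_oc, fit$r_ob, fit$r_bo)
}
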