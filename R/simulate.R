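#' Synthetic macroscopic current trace
#'
#' Generates a raw (un-normalized) macroscopic current time course by scaling
#' a scheme's normalized prediction by an amplitude and adding stationary
#' Gaussian noise. With zero noise and unit amplitude the output equals the
#' [integrate_protocol()] trace.
#'
#' @inheritParams integrate_protocol
#' @param amplitude Pre-drug steady-state current (A or any unit).
#' @param noise_sd Gaussian noise standard deviation, in the same units.
#' @param seed Integer seed; generation is a deterministic function of
#'   (parameters, seed).
#'
#' @return A tibble with `time_s` and `current`, with the generating
#'   scheme/params/protocol stored as attributes.
#' @export
sim_macroscopic_trace <- function(scheme, params, protocol, amplitude = 1,
                                  noise_sd = 0, seed = 1, dt = 0.01,
                                  out_dt = 0.5) {
  tr <- integrate_protocol(scheme, params, protocol, dt = dt, out_dt = out_dt)
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(nrow(tr), 0, noise_sd))
  } else {
    0
  }
  out <- tibble(time_s = tr$time_s, current = amplitude * tr$i_norm + noise)
  attributes(out)[c("scheme", "params", "protocol")] <-
    attributes(tr)[c("scheme", "params", "protocol")]
  out
}

# simulate one C-O-B channel's state/dwell sequence up to `duration`
# (preallocated, grows geometrically)
sim_cob_dwells_one <- function(r_co, r_oc, r_ob, r_bo, duration) {
  # states: 1 closed, 2 open, 3 blocked; start from the stationary distribution
  pi0 <- cob_stationary(r_co, r_oc, r_ob, r_bo)
  state <- sample(1:3, 1, prob = pi0)
  lam_open <- r_oc + r_ob
  rates <- c(r_co, lam_open, r_bo)
  cap <- 4096L
  states <- integer(cap)
  dwells <- numeric(cap)
  n <- 0L
  total <- 0
  while (total < duration) {
    d <- stats::rexp(1, rates[state])
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(states) <- cap
      length(dwells) <- cap
    }
    states[n] <- state
    dwells[n] <- d
    total <- total + d
    state <- if (state == 1L) 2L
             else if (state == 3L) 2L
             else if (stats::runif(1) < r_oc / lam_open) 1L else 3L
  }
  dwells[n] <- dwells[n] - (total - duration)
  list(state = states[seq_len(n)], dwell = dwells[seq_len(n)])
}

#' Synthetic C-O-B single-channel event list
#'
#' Continuous-time Markov simulation of one closed-open-blocked channel,
#' collapsed to conductance levels (closed/blocked -> 0, open -> 1) and
#' dead-time concatenated, i.e. the event list a perfect half-amplitude
#' idealization of the record would produce.
#'
#' @inheritParams burst_summary
#' @param duration Record length (s).
#' @param seed Integer seed.
#' @param dead_time Dead time used for concatenation (s); 0 keeps every dwell.
#' @return An `event_list` tibble (`level`, `duration_s`).
#' @export
sim_cob_events <- function(r_co, r_oc, r_ob, r_bo, duration, seed = 1,
                           dead_time = .const$dead_time) {
  if (any(c(r_co, r_oc, r_bo) <= 0) || r_ob < 0) abort("rates must be positive")
  sim <- withr::with_seed(seed,
                          sim_cob_dwells_one(r_co, r_oc, r_ob, r_bo, duration))
  lv <- ifelse(sim$state == 2L, 1L, 0L)
  r <- rle(lv)
  # collapse adjacent same-level dwells (blocked and closed share level 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- c(0, cumsum(sim$dwell))
  du <- cs[ends + 1L] - cs[starts]
  if (dead_time > 0) {
    m <- apply_dead_time(r$values, du, dead_time)
    new_event_list(m$level, m$duration, dead_time, 1L)
  } else {
    new_event_list(r$values, du, 0, 1L)
  }
}

#' Synthetic multi-channel current trace from a C-O-B scheme
#'
#' Simulates `n_channels` independent C-O-B channels, sums their unitary
#' currents, samples the result on a uniform grid, and adds Gaussian noise.
#'
#' @inheritParams burst_summary
#' @param n_channels Number of independent channels.
#' @param duration Record length (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param unitary_current Single-channel current amplitude.
#' @param noise_sd Gaussian noise standard deviation (same units).
#' @param seed Integer seed.
#' @return A tibble with `time_s` and `current`.
#' @export
sim_single_channel_trace <- function(r_co, r_oc, r_ob, r_bo, n_channels = 1,
                                     duration = 100, sampling_rate = 1000,
                                     unitary_current = 1, noise_sd = 0,
                                     seed = 1) {
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  withr::with_seed(seed, {
    level <- numeric(length(t))
    for (ch in seq_len(n_channels)) {
      sim <- sim_cob_dwells_one(r_co, r_oc, r_ob, r_bo, duration)
      ends <- cumsum(sim$dwell)
      idx <- findInterval(t, c(0, ends), rightmost.closed = TRUE)
      idx[idx < 1] <- 1
      idx[idx > length(sim$state)] <- length(sim$state)
      level <- level + (sim$state[idx] == 2L)
    }
    current <- unitary_current * level +
      if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
    tibble(time_s = t, current = current)
  })
}

#' Synthetic dose-response table from the modified Hill equation
#'
#' Draws `replicates` stimulation values per concentration from the modified
#' Hill curve with multiplicative Gaussian noise of coefficient of variation
#' `noise_cv`, and returns per-concentration means with SEM and n, the format
#' a dose-response experiment produces.
#'
#' @param k_half Midpoint concentration `K_0.5` (M).
#' @param n_hill Hill coefficient.
#' @param imax_ratio Maximal fractional stimulation `Imax/Icontrol`.
#' @param conc Concentration grid (M).
#' @param replicates Replicates per concentration.
#' @param noise_cv Multiplicative noise CV (0 for exact curve values).
#' @param seed Integer seed.
#' @return A tibble with `conc_M`, `stimulation` (mean), `sem`, `n`.
#' @export
sim_dose_response <- function(k_half, n_hill, imax_ratio, conc,
                              replicates = 5, noise_cv = 0.05, seed = 1) {
  if (k_half <= 0 || n_hill <= 0 || imax_ratio < 1) {
    abort("Hill parameters must satisfy k_half > 0, n_hill > 0, imax_ratio >= 1")
  }
  mu <- (k_half^n_hill + imax_ratio * conc^n_hill) /
    (k_half^n_hill + conc^n_hill)
  withr::with_seed(seed, {
    purrr::map2_dfr(conc, mu, function(cc, m) {
      reps <- if (noise_cv > 0) {
        m * (1 + stats::rnorm(replicates, 0, noise_cv))
      } else {
        rep(m, replicates)
      }
      tibble(conc_M = cc, stimulation = mean(reps),
             sem = if (replicates > 1) sd(reps) / sqrt(replicates) else NA_real_,
             n = replicates)
    })
  })
}

#' Synthetic 1-octanol extraction experiment
#'
#' Forward-simulates the spectrophotometric readout of a 20:1 extraction of a
#' saturated aqueous drug solution: the first extract's optical density is
#' the calibration line evaluated at `s_true * concentration_factor`, the
#' second extract (all drug already removed) reads at blank level; Gaussian
#' OD noise optional.
#'
#' @param s_true True aqueous solubility (M).
#' @param concentration_factor Extraction volume ratio (e.g. 20).
#' @param cal A [fit_calibration()] result (or compatible list with `slope`,
#'   `intercept`).
#' @param noise_sd OD noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble with `extract` (1, 2) and `od`.
#' @export
sim_extraction <- function(s_true, concentration_factor, cal, noise_sd = 0,
                           seed = 1) {
  if (s_true < 0 || concentration_factor <= 0) {
    abort("`s_true` must be >= 0 and `concentration_factor` > 0")
  }
  od1 <- cal$intercept + cal$slope * s_true * concentration_factor
  od2 <- cal$intercept
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(2, 0, noise_sd))
  } else {
    c(0, 0)
  }
  tibble(extract = c(1L, 2L), od = c(od1, od2) + noise)
}
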