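#' Normalize a raw current trace to its pre-drug steady state
#'
#' Divides the current by its mean over a pre-drug window, so the normalized
#' trace averages 1 before drug exposure, the convention all model
#' predictions use.
#'
#' @param data Data frame with time and current columns.
#' @param pre_drug_window Length-2 interval (s) preceding drug onset.
#' @param time,current Column names (tidy-eval); defaults `time_s`, `current`.
#'
#' @return A tibble with `time_s` and `i_norm`.
#' @export
normalize_trace <- function(data, pre_drug_window, time = time_s,
                            current = current) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ current }})
  if (length(pre_drug_window) != 2 || diff(pre_drug_window) <= 0) {
    abort("`pre_drug_window` must be an increasing length-2 interval")
  }
  m <- window_mean(t, y, pre_drug_window, "pre-drug")
  if (m <= 0) abort("pre-drug mean current is not positive; cannot normalize")
  tibble(time_s = t, i_norm = y / m)
}

#' Channel binding-site concentration in a membrane compartment
#'
#' `C_t = N / (N_A * volume)`: the molar concentration that `n` channels give
#' in the stated compartment volume (1e-16 L for the whole patch membrane,
#' 5e-17 L for the outer leaflet).
#'
#' @param n Number of channels in the patch.
#' @param volume Compartment volume (L).
#' @return Concentration `C_t` (M).
#' @export
#' @examples
#' channel_site_concentration(100, 1e-16)  # 1.66e-6 M
channel_site_concentration <- function(n, volume) {
  if (n < 1 || volume <= 0) abort("`n` must be >= 1 and `volume` > 0")
  n / (.const$N_avogadro * volume)
}

#' Channel count from the pre-drug mean current
#'
#' Estimates the number of channels in a patch as
#' `N = mean_current / (unitary_current * po_bas)`, rounded, using the basal
#' open probability of prephosphorylated channels in ATP (default 0.16).
#'
#' @param pre_drug_mean_current Mean steady current before the drug (A).
#' @param unitary_current Single-channel current (A).
#' @param po_bas Basal open probability, in (0, 1].
#' @return Integer channel count (>= 1).
#' @export
estimate_channel_count <- function(pre_drug_mean_current, unitary_current,
                                   po_bas = .const$po_basal) {
  if (pre_drug_mean_current <= 0 || unitary_current <= 0 ||
      po_bas <= 0 || po_bas > 1) {
    abort("currents must be positive and `po_bas` in (0, 1]")
  }
  max(1L, as.integer(round(pre_drug_mean_current / (unitary_current * po_bas))))
}

#' Bundle normalized traces for an ensemble fit
#'
#' Builds the trace-set tibble [fit_ensemble()] consumes: one row per
#' normalized trace, with its drug protocol alongside.
#'
#' @param traces List of normalized traces (tibbles with `time_s`, `i_norm`).
#' @param protocols List of [drug_protocol()]s, one per trace.
#' @return A tibble with columns `trace_id`, `protocol` (list), `data` (list).
#' @export
trace_set <- function(traces, protocols) {
  if (length(traces) != length(protocols)) {
    abort("`traces` and `protocols` must have the same length")
  }
  if (length(traces) == 0) abort("a trace set needs at least one trace")
  protocols <- purrr::map(protocols, check_protocol)
  purrr::walk(traces, function(tr) {
    if (!all(c("time_s", "i_norm") %in% names(tr))) {
      abort("each trace needs columns `time_s` and `i_norm`")
    }
    if (any(diff(tr$time_s) <= 0)) abort("trace time grids must be strictly increasing")
  })
  tibble(trace_id = seq_along(traces), protocol = protocols, data = traces)
}

#' Configuration for a global ensemble fit
#'
#' @param scheme Scheme id, 1-4.
#' @param n_channels Channel count in the patch (sets `C_t`).
#' @param d_ratio Partition constraint `k_in / k_out`; default the measured
#'   octanol/water distribution coefficient 62580.
#' @param volume Target-compartment volume (L); defaults to 1e-16 L for
#'   schemes 1/3 and 5e-17 L for schemes 2/4.
#' @param init Optional named list of starting values for the free parameters
#'   (`k_out`, `k_on`, `k_off`, `po_ratio`, and `k_flip` for schemes 2/4).
#' @param dt Integration step (s).
#' @param reltol Relative SSE convergence tolerance of the simplex.
#' @param maxit Maximum objective evaluations per simplex run.
#' @param seed Seed for the jittered restart taken if the simplex collapses.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(scheme, n_channels, d_ratio = .const$D_oct_wat,
                       volume = NULL, init = NULL, dt = 0.01,
                       reltol = 1e-8, maxit = 5000, seed = 1) {
  scheme <- check_scheme(scheme)
  if (d_ratio <= 0) abort("`d_ratio` must be positive")
  if (n_channels < 1) abort("`n_channels` must be >= 1")
  if (is.null(volume)) {
    volume <- if (scheme_two_compartment(scheme)) .const$leaflet_volume
              else .const$membrane_volume
  }
  structure(list(scheme = scheme, n_channels = as.integer(n_channels),
                 d_ratio = d_ratio, volume = volume, init = init, dt = dt,
                 reltol = reltol, maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "fit_config")
}

free_param_names <- function(scheme) {
  c("k_out", "k_on", "k_off", "po_ratio",
    if (scheme_two_compartment(scheme)) "k_flip")
}

# free-parameter vector (natural scale, named) -> gating_params under the
# k_in = d_ratio * k_out constraint
build_params <- function(free, config) {
  gating_params(
    k_in = config$d_ratio * free[["k_out"]],
    k_out = free[["k_out"]], k_on = free[["k_on"]], k_off = free[["k_off"]],
    po_ratio = free[["po_ratio"]],
    c_t = channel_site_concentration(config$n_channels, config$volume),
    k_flip = if (scheme_two_compartment(config$scheme)) free[["k_flip"]] else NULL
  )
}

#' Ensemble sum-of-squares objective
#'
#' The plain (unweighted) least-squares objective of a global fit: for each
#' trace the chosen scheme is integrated over that trace's protocol, the
#' prediction is linearly interpolated onto the observed time grid, and
#' squared residuals are summed over all traces and samples. `k_in` is
#' reconstructed from the partition constraint as `d_ratio * k_out` for every
#' evaluation.
#'
#' @param free Named numeric vector of free parameters (`k_out`, `k_on`,
#'   `k_off`, `po_ratio`, plus `k_flip` for schemes 2/4), natural scale.
#' @param traces A [trace_set()] tibble.
#' @param config A [fit_config()].
#' @return Sum of squared residuals.
#' @export
ensemble_objective <- function(free, traces, config) {
  if (nrow(traces) == 0) abort("empty trace set")
  params <- build_params(free, config)
  total <- 0
  for (i in seq_len(nrow(traces))) {
    obs <- traces$data[[i]]
    grid_dt <- min(diff(obs$time_s))
    pred <- integrate_protocol(config$scheme, params, traces$protocol[[i]],
                               dt = config$dt, out_dt = max(config$dt, grid_dt / 2))
    fit_i <- approx(pred$time_s, pred$i_norm, xout = obs$time_s, rule = 2)$y
    total <- total + sum((fit_i - obs$i_norm)^2)
  }
  total
}

#' Global ensemble fit of a gating scheme by downhill simplex
#'
#' Fits one scheme simultaneously to a set of normalized on/off current time
#' courses by simple least squares, with rate constants optimized in log
#' space (guaranteeing positivity) under the partition constraint
#' `k_in = d_ratio * k_out`, using the Nelder-Mead downhill simplex. The
#' simplex is restarted from its own optimum until the relative SSE
#' improvement drops below `reltol`; a degenerate run triggers one seeded,
#' jittered restart.
#'
#' @param traces A [trace_set()] tibble; at least one on- and one off-
#'   relaxation should be present for identifiability (a warning is raised
#'   otherwise).
#' @param config A [fit_config()].
#' @return An object of class `ensemble_fit`: `params` ([gating_params()]),
#'   `sse`, `derived` (the [derived_affinities()] tibble), `converged`,
#'   `n_evaluations`, plus the inputs.
#' @export
#' @examples
#' \donttest{
#' p <- gating_params(k_in = 4034, k_out = 0.06446, k_on = 870.3,
#'                    k_off = 0.007451, po_ratio = 3.935, c_t = 1.66e-6)
#' prot <- drug_protocol(c(600, 600), x_saturated = c(1, 0))
#' tr <- integrate_protocol(3, p, prot)
#' fit <- fit_ensemble(trace_set(list(tr), list(prot)),
#'                     fit_config(3, n_channels = 100))
#' }
fit_ensemble <- function(traces, config) {
  if (!inherits(config, "fit_config")) abort("`config` must be a fit_config")
  if (nrow(traces) == 0) abort("a trace set needs at least one trace")
  has_on <- any(purrr::map_lgl(traces$protocol, ~ any(.x$conc_M > 0)))
  has_off <- any(purrr::map_lgl(traces$protocol,
                                ~ any(.x$conc_M == 0 & seq_len(nrow(.x)) > 1)))
  if (!has_on || !has_off) {
    warn("trace set lacks an on- or off-relaxation; partition and binding rates may not be identifiable")
  }

  nm <- free_param_names(config$scheme)
  init <- list(k_out = 0.1, k_on = 1e3, k_off = 0.01,
               po_ratio = max(purrr::map_dbl(traces$data, ~ max(.x$i_norm)), 1.1),
               k_flip = 0.1)
  init[names(config$init %||% list())] <- config$init
  start <- log(unlist(init[nm]))

  obj <- function(lp) {
    free <- setNames(exp(lp), nm)
    if (free[["po_ratio"]] < 1) return(1e10)
    tryCatch(ensemble_objective(free, traces, config),
             error = function(e) 1e10)
  }

  n_eval <- 0L
  run <- function(par) {
    o <- optim(par, obj, method = "Nelder-Mead",
               control = list(maxit = config$maxit, reltol = config$reltol))
    n_eval <<- n_eval + o$counts[["function"]]
    o
  }

  o <- run(start)
  converged <- FALSE
  for (round in 1:8) {
    prev <- o$value
    o2 <- run(o$par)
    improve <- (prev - o2$value) / max(prev, .Machine$double.eps)
    o <- o2
    if (improve < config$reltol) { converged <- TRUE; break }
  }
  if (!converged || o$convergence != 0) {
    # degenerate or stalled simplex: one seeded, jittered restart
    jitter <- withr::with_seed(config$seed,
                               stats::rnorm(length(start), 0, 0.1))
    o3 <- run(o$par + jitter)
    if (o3$value < o$value) o <- o3
    converged <- o$convergence == 0
  }

  free <- setNames(exp(o$par), nm)
  params <- build_params(free, config)
  structure(
    list(params = params, sse = o$value,
         derived = derived_affinities(config$scheme, params),
         converged = converged, n_evaluations = n_eval,
         config = config, traces = traces),
    class = "ensemble_fit"
  )
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> scheme %d, %d trace(s), SSE = %.4g%s\n",
              x$config$scheme, nrow(x$traces), x$sse,
              if (x$converged) "" else " [not converged]"))
  print(x$params)
  cat(sprintf("  K_d_mem = %.4g M, K_0.5_mem = %.4g M, K_0.5_aq = %.4g M\n",
              x$derived$k_d_mem, x$derived$k_half_mem, x$derived$k_half_aq))
  invisible(x)
}

# fitted normalized traces of an ensemble fit, one tibble row per sample
fitted_traces <- function(fit) {
  purrr::map_dfr(seq_len(nrow(fit$traces)), function(i) {
    obs <- fit$traces$data[[i]]
    pred <- integrate_protocol(fit$config$scheme, fit$params,
                               fit$traces$protocol[[i]], dt = fit$config$dt,
                               out_dt = max(fit$config$dt,
                                            min(diff(obs$time_s)) / 2))
    tibble(trace_id = fit$traces$trace_id[i], time_s = obs$time_s,
           observed = obs$i_norm,
           predicted = approx(pred$time_s, pred$i_norm,
                              xout = obs$time_s, rule = 2)$y)
  })
}
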