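#' Time derivative of a scheme's state vector
#'
#' Evaluates the right-hand side of the chosen scheme's dynamic equations at a
#' given state and cytosolic drug concentration. State-vector conventions
#' (all concentrations, M):
#' * scheme 1: `x1` free drug in the membrane, `x2` unliganded channels;
#' * scheme 2: `x1` inner-leaflet drug, `x2` outer-leaflet drug,
#'   `x3` unliganded channels;
#' * scheme 3: `x1` free drug, `x2` unliganded, `x3` monoliganded channels;
#' * scheme 4: `x1` inner-leaflet drug, `x2` outer-leaflet drug,
#'   `x3` unliganded, `x4` monoliganded channels.
#'
#' The diliganded (potentiated) channel concentration of the two-site schemes
#' is implicit, `c_t - unliganded - monoliganded`, so channel mass is
#' conserved by construction.
#'
#' @param scheme Scheme id, 1-4.
#' @param params A [gating_params()] object valid for the scheme.
#' @param state Numeric state vector of the scheme's dimension (2, 3, 3, 4).
#' @param v_c Cytosolic drug concentration (M).
#'
#' @return Numeric vector of time derivatives (M/s).
#' @export
#' @examples
#' p <- gating_params(k_in = 4034, k_out = 0.06446, k_on = 870.3,
#'                    k_off = 0.007451, po_ratio = 3.935, c_t = 1.66e-6)
#' scheme_rhs(3, p, state = c(0, p$c_t, 0), v_c = 62e-9)
scheme_rhs <- function(scheme, params, state, v_c) {
  scheme <- check_scheme(scheme)
  check_params(params, scheme)
  if (length(state) != scheme_dim(scheme)) {
    abort(sprintf("scheme %d needs a state vector of length %d, got %d",
                  scheme, scheme_dim(scheme), length(state)))
  }
  if (any(state < 0)) abort("state components must be non-negative")
  .heun_rhs(scheme, as.numeric(state), params$k_in, params$k_out, params$k_on,
            params$k_off, params$k_flip %||% 0, params$c_t, v_c)
}

#' Normalized current predicted from a state vector
#'
#' The macroscopic current normalized to the pre-drug steady state is
#' `f + (1 - f) * po_ratio`, where `f` is the fraction of channels not in the
#' potentiated class: unliganded for schemes 1-2, unliganded + monoliganded
#' for schemes 3-4.
#'
#' @inheritParams scheme_rhs
#' @return Dimensionless current in `[1, po_ratio]`.
#' @export
normalized_current <- function(scheme, params, state) {
  scheme <- check_scheme(scheme)
  check_params(params, scheme)
  if (is.vector(state)) state <- matrix(state, nrow = 1)
  if (ncol(state) != scheme_dim(scheme)) {
    abort(sprintf("scheme %d needs %d state components", scheme,
                  scheme_dim(scheme)))
  }
  f <- switch(scheme,
              state[, 2] / params$c_t,
              state[, 3] / params$c_t,
              (state[, 2] + state[, 3]) / params$c_t,
              (state[, 3] + state[, 4]) / params$c_t)
  unname(f + (1 - f) * params$po_ratio)
}

# largest effective first-order rate in the system, used to cap dt
fastest_rate <- function(scheme, params, v_c_max) {
  vm <- max(unlist(steady_state_concentrations(scheme, params, v_c_max)), 0)
  max(2 * params$k_out,
      params$k_on * vm,
      params$k_on * params$c_t,
      params$k_off,
      if (!is.null(params$k_flip)) 2 * params$k_flip else 0)
}

#' Integrate a scheme over a drug-application protocol
#'
#' Solves the scheme's dynamic equations over a piecewise-constant cytosolic
#' drug protocol with Heun's predictor-corrector (second-order "modified
#' Euler") method, and returns the normalized current time course. Drug
#' compartments start empty and all channels unliganded, so the normalized
#' current starts at exactly 1; the state is carried continuously across
#' segment boundaries.
#'
#' The step size is capped at `0.1 / r_max`, where `r_max` is the fastest
#' effective first-order rate at the protocol's highest concentration, so the
#' stiffest term is resolved with at least ten steps per time constant.
#'
#' @inheritParams scheme_rhs
#' @param protocol A [drug_protocol()].
#' @param dt Integration step (s); default 0.01, reduced automatically when
#'   the rates demand it.
#' @param out_dt Output sampling interval (s); default 0.5.
#' @param x0 Optional initial state; defaults to the pre-drug steady state
#'   described above.
#'
#' @return A tibble of class `simulated_trace` with columns `time_s` and
#'   `i_norm`, plus the state trajectory in attribute `"states"`, the final
#'   state in `"final_state"`, and the scheme/parameters/protocol as
#'   attributes.
#' @export
#' @examples
#' p <- gating_params(k_in = 4034, k_out = 0.06446, k_on = 870.3,
#'                    k_off = 0.007451, po_ratio = 3.935, c_t = 1.66e-6)
#' tr <- integrate_protocol(3, p, drug_protocol(c(600, 600), x_saturated = c(1, 0)))
#' tail(tr)
integrate_protocol <- function(scheme, params, protocol, dt = 0.01,
                               out_dt = 0.5, x0 = NULL) {
  scheme <- check_scheme(scheme)
  check_params(params, scheme)
  protocol <- check_protocol(protocol)
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be positive")
  dt <- min(dt, 0.1 / fastest_rate(scheme, params, max(protocol$conc_M)))
  if (is.null(x0)) x0 <- initial_state(scheme, params)
  thin <- max(1L, as.integer(round(out_dt / dt)))
  res <- .heun_integrate(scheme, as.numeric(x0), protocol$duration_s,
                         protocol$conc_M, params$k_in, params$k_out,
                         params$k_on, params$k_off, params$k_flip %||% 0,
                         params$c_t, params$po_ratio, dt, thin)
  out <- tibble(time_s = res$t, i_norm = res$i_norm)
  structure(out,
            class = c("simulated_trace", class(out)),
            states = res$states, final_state = res$final_state,
            scheme = scheme, params = params, protocol = protocol,
            dt = dt)
}

#' Steady-state intramembrane drug concentration(s)
#'
#' Closed-form steady state of the drug compartments under constant cytosolic
#' concentration `v_c` and a drug-free pipette: for the one-compartment
#' schemes (1, 3) the membrane concentration is `v_c * k_in / (2 * k_out)`;
#' for the two-compartment schemes (2, 4) the cytosolic- and external-leaflet
#' concentrations are
#' `v_c * (k_in/k_out) * (k_out + k_flip) / (k_out + 2*k_flip)` and
#' `v_c * (k_in/k_out) * k_flip / (k_out + 2*k_flip)`.
#'
#' @inheritParams scheme_rhs
#' @return For schemes 1/3 a named list with `v_m`; for schemes 2/4 a named
#'   list with `v_mc` (cytosolic leaflet) and `v_me` (external leaflet), M.
#' @export
steady_state_concentrations <- function(scheme, params, v_c) {
  scheme <- check_scheme(scheme)
  check_params(params, scheme)
  if (!scheme_two_compartment(scheme)) {
    list(v_m = v_c * params$k_in / (2 * params$k_out))
  } else {
    kf <- params$k_flip
    ko <- params$k_out
    base <- v_c * (params$k_in / ko) / (ko + 2 * kf)
    list(v_mc = base * (ko + kf), v_me = base * kf)
  }
}

# drug concentration in the channel-bearing compartment at steady state
target_concentration <- function(scheme, params, v_c) {
  ss <- steady_state_concentrations(scheme, params, v_c)
  if (scheme_two_compartment(scheme)) ss$v_me else ss$v_m
}

#' Steady-state normalized current
#'
#' Closed-form steady-state response: `1 + (po_ratio - 1) * Y`, where `Y` is
#' the equilibrium occupancy of the potentiated class at the steady-state
#' target-compartment drug concentration `V`: `Y1 = V / (K_d_mem + V)` for the
#' single-site schemes (1, 2), `Y2 = (V / (K_d_mem + V))^2` for the two-site
#' schemes (3, 4), with `K_d_mem = k_off / k_on`.
#'
#' @inheritParams scheme_rhs
#' @param v_c Cytosolic drug concentration(s), M; vectorized.
#' @return Normalized steady current, in `[1, po_ratio]`.
#' @export
steady_state_response <- function(scheme, params, v_c) {
  scheme <- check_scheme(scheme)
  check_params(params, scheme)
  v <- vapply(v_c, function(vc) target_concentration(scheme, params, vc),
              numeric(1))
  kd <- params$k_off / params$k_on
  y <- v / (kd + v)
  if (scheme_two_site(scheme)) y <- y^2
  1 + (params$po_ratio - 1) * y
}

#' Intramembrane and apparent aqueous affinities
#'
#' Derived affinity measures of a parameter set: the intramembrane
#' dissociation constant `K_d_mem = k_off / k_on`; the intramembrane
#' half-maximal concentration `K_0.5_mem`, equal to `K_d_mem` for the
#' single-site schemes and `(1 + sqrt(2)) * K_d_mem` for the two-site schemes;
#' and the apparent aqueous affinity `K_0.5_aq`, obtained by dividing
#' `K_0.5_mem` by the steady-state membrane/water concentration ratio
#' (`k_in / (2 k_out)` for schemes 1/3;
#' `(k_in/k_out) * k_flip / (k_out + 2 k_flip)` for schemes 2/4).
#'
#' @inheritParams scheme_rhs
#' @return A tibble with columns `k_d_mem`, `k_half_mem`, `k_half_aq` (M).
#' @export
#' @examples
#' p <- gating_params(k_in = 4034, k_out = 0.06446, k_on = 870.3,
#'                    k_off = 0.007451, po_ratio = 3.935, c_t = 1.66e-6)
#' derived_affinities(3, p)   # K_0.5_aq ~ 0.66 nM
derived_affinities <- function(scheme, params) {
  scheme <- check_scheme(scheme)
  check_params(params, scheme)
  kd <- params$k_off / params$k_on
  k_half_mem <- if (scheme_two_site(scheme)) (1 + sqrt(2)) * kd else kd
  partition <- if (scheme_two_compartment(scheme)) {
    (params$k_in / params$k_out) * params$k_flip /
      (params$k_out + 2 * params$k_flip)
  } else {
    params$k_in / (2 * params$k_out)
  }
  tibble(k_d_mem = kd, k_half_mem = k_half_mem,
         k_half_aq = k_half_mem / partition)
}

#' Midpoint Hill slope of a scheme's steady-state dose-response curve
#'
#' The logit-slope of the steady-state activation curve at its midpoint:
#' exactly 1 for the single-site schemes, and `2 * (2 - sqrt(2))` (about
#' 1.1716) for the two-site schemes, whose fractional response
#' `Y2 = (V/(K_d+V))^2` rises less steeply than a two-site Hill function
#' because singly liganded channels are silent but populated.
#'
#' @param scheme Scheme id, 1-4.
#' @return Dimensionless midpoint slope.
#' @export
midpoint_hill_slope <- function(scheme) {
  if (scheme_two_site(check_scheme(scheme))) 2 * (2 - sqrt(2)) else 1
}
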