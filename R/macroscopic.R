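window_mean <- function(t, y, window, what) {
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) abort(sprintf("%s window [%g, %g] contains no samples",
                               what, window[1], window[2]))
  mean(y[sel])
}

#' Fractional current stimulation by a drug application
#'
#' Mean steady current during the drug application divided by the average of
#' the pre- and post-drug mean steady currents. Using both flanking windows
#' compensates for slow rundown.
#'
#' @param data Data frame with time and current columns.
#' @param pre_window,drug_window,post_window Length-2 numeric intervals (s),
#'   disjoint and ordered, marking the three steady-state stretches.
#' @param time,current Column names (tidy-eval); defaults `time_s`, `current`.
#'
#' @return Fractional stimulation `I / I_control` (dimensionless).
#' @export
fractional_stimulation <- function(data, pre_window, drug_window, post_window,
                                   time = time_s, current = current) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ current }})
  w <- list(pre = pre_window, drug = drug_window, post = post_window)
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || diff(w[[nm]]) <= 0) {
      abort(sprintf("`%s_window` must be an increasing length-2 interval", nm))
    }
  }
  if (pre_window[2] > drug_window[1] || drug_window[2] > post_window[1]) {
    abort("windows must be disjoint and ordered pre < drug < post")
  }
  denom <- 0.5 * (window_mean(t, y, pre_window, "pre") +
                    window_mean(t, y, post_window, "post"))
  if (denom == 0) abort("pre/post mean current is zero; cannot normalize")
  window_mean(t, y, drug_window, "drug") / denom
}

#' Fit the modified Hill equation to dose-response data
#'
#' Least-squares fit of
#' `I/I_control = (K^n + (Imax/Icontrol) * c^n) / (K^n + c^n)`,
#' which equals 1 at zero concentration and `Imax/Icontrol` at saturation by
#' construction, with `K_0.5`, `n`, and `Imax/Icontrol` free.
#'
#' @param data Data frame of dose-response points.
#' @param conc,stimulation Column names (tidy-eval) for aqueous concentration
#'   (M) and fractional stimulation; defaults `conc_M`, `stimulation`.
#'
#' @return An object of class `hill_fit`: list with `k_half` (M), `n_hill`,
#'   `imax_ratio`, `sse`, `fitted`, `data`.
#' @export
#' @examples
#' d <- sim_dose_response(k_half = 1.5e-9, n_hill = 1.2, imax_ratio = 11.5,
#'                        conc = 10^seq(-10.3, -7.3, length.out = 8),
#'                        replicates = 5, noise_cv = 0.05, seed = 7)
#' fit_hill(d)
fit_hill <- function(data, conc = conc_M, stimulation = stimulation) {
  cc <- dplyr::pull(data, {{ conc }})
  y <- dplyr::pull(data, {{ stimulation }})
  keep <- is.finite(cc) & is.finite(y) & cc > 0
  cc <- cc[keep]; y <- y[keep]
  if (length(cc) < 4) abort("need at least 4 dose-response points with positive concentration")
  if (diff(range(log10(cc))) < 1) {
    warn("dose-response points span less than one decade; the fit may be poorly constrained")
  }
  if (diff(range(y)) < .Machine$double.eps^0.5 * max(abs(y))) {
    abort("all stimulation values are equal; the Hill fit is degenerate")
  }

  imax0 <- max(max(y), 1.05)
  mid0 <- (1 + imax0) / 2
  k0 <- cc[which.min(abs(y - mid0))]
  if (min(y) > mid0) warn("no point below the apparent midpoint; K_0.5 is an extrapolation")
  if (max(y) < mid0) warn("no point above the apparent midpoint; K_0.5 is an extrapolation")

  df <- data.frame(cc = cc, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ (k^n + imax * cc^n) / (k^n + cc^n),
    data = df,
    start = list(k = k0, n = 1, imax = imax0),
    lower = c(k = min(cc) * 1e-4, n = 0.05, imax = 1),
    upper = c(k = max(cc) * 1e4, n = 20, imax = 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  est <- coef(fit)
  structure(
    list(k_half = unname(est["k"]), n_hill = unname(est["n"]),
         imax_ratio = unname(est["imax"]),
         sse = sum(residuals(fit)^2), fit = fit,
         data = tibble(conc_M = cc, stimulation = y)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_0.5 = %.3g M, n = %.3f, Imax/Icontrol = %.3f (SSE %.3g)\n",
              x$k_half, x$n_hill, x$imax_ratio, x$sse))
  invisible(x)
}

#' Single-exponential fit to a deactivation time course
#'
#' Fits `a + b * exp(-(t - t0) / tau)` to a current segment following drug
#' removal; the deactivation rate is `1/tau`. The offset `a` is free because
#' the current relaxes back to its pre-drug baseline, not to zero. A segment
#' that does not decay is returned flagged rather than as an error.
#'
#' @param data Data frame with the post-removal segment.
#' @param time,current Column names (tidy-eval); defaults `time_s`, `i_norm`.
#'
#' @return An object of class `decay_fit`: `tau_off` (s), `rate_off` (s^-1),
#'   `a`, `b`, `sse`, `flagged`.
#' @export
fit_exponential_decay <- function(data, time = time_s, current = i_norm) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ current }})
  if (length(t) < 20) abort("need at least 20 samples after drug removal")
  tt <- t - t[1]
  flagged_result <- function() {
    structure(list(tau_off = NA_real_, rate_off = NA_real_, a = NA_real_,
                   b = NA_real_, sse = NA_real_, flagged = TRUE),
              class = "decay_fit")
  }
  span <- diff(range(y))
  if (span < 1e-12 * max(abs(y), 1) ||
      mean(y[seq_len(max(3, length(y) %/% 10))]) <=
        mean(y[seq.int(length(y) - max(3, length(y) %/% 10) + 1, length(y))])) {
    return(flagged_result())
  }
  a0 <- min(y)
  b0 <- y[1] - a0
  # crude tau from the 1/e crossing
  target <- a0 + b0 / exp(1)
  idx <- which(y <= target)[1]
  tau0 <- if (is.na(idx)) diff(range(tt)) / 2 else max(tt[idx], diff(tt)[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a + b * exp(-tt / tau),
      data = data.frame(tt = tt, y = y),
      start = list(a = a0, b = b0, tau = tau0),
      lower = c(a = -Inf, b = 0, tau = diff(tt)[1] * 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(flagged_result())
  est <- coef(fit)
  structure(
    list(tau_off = unname(est["tau"]), rate_off = 1 / unname(est["tau"]),
         a = unname(est["a"]), b = unname(est["b"]),
         sse = sum(residuals(fit)^2), flagged = FALSE),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$flagged) cat("<decay_fit> flagged: segment does not decay\n")
  else cat(sprintf("<decay_fit> tau_off = %.4g s (rate %.4g s^-1), offset %.4g\n",
                   x$tau_off, x$rate_off, x$a))
  invisible(x)
}

# Occupancies of the irreversible chain S1 -> S2 -> S3 -> S4 at times t,
# by partial fractions of the Laplace transforms; repeated rates (within
# `tol` relative) take the confluent (L'Hopital) branches.
chain_occupancies <- function(t, k12, k23, k34, tol = 1e-6) {
  near <- function(a, b) abs(a - b) <= tol * max(a, b)
  p1 <- exp(-k12 * t)
  p2 <- if (near(k12, k23)) {
    k12 * t * exp(-k12 * t)
  } else {
    k12 / (k23 - k12) * (exp(-k12 * t) - exp(-k23 * t))
  }
  N <- k12 * k23
  r <- c(k12, k23, k34)
  if (near(k12, k23) && near(k23, k34)) {
    a <- mean(r)
    p3 <- N * t^2 / 2 * exp(-a * t)
  } else if (near(k12, k23) || near(k12, k34) || near(k23, k34)) {
    # one repeated root `a` (multiplicity 2), one simple root `b`
    if (near(k12, k23)) { a <- (k12 + k23) / 2; b <- k34 }
    else if (near(k12, k34)) { a <- (k12 + k34) / 2; b <- k23 }
    else { a <- (k23 + k34) / 2; b <- k12 }
    d <- b - a
    p3 <- N * (-exp(-a * t) / d^2 + t * exp(-a * t) / d + exp(-b * t) / d^2)
  } else {
    p3 <- N * (exp(-r[1] * t) / ((r[2] - r[1]) * (r[3] - r[1])) +
                 exp(-r[2] * t) / ((r[1] - r[2]) * (r[3] - r[2])) +
                 exp(-r[3] * t) / ((r[1] - r[3]) * (r[2] - r[3])))
  }
  p4 <- 1 - p1 - p2 - p3
  cbind(p1 = p1, p2 = p2, p3 = p3, p4 = pmax(p4, 0))
}

#' Empirical three-step fit to an activation time course
#'
#' Fits the normalized current rise after drug addition to an irreversible
#' three-step chain `S1 -> S2 -> S3 -> S4` whose compound states S1-S3 gate at
#' the basal open probability (normalized level 1) while S4 gates at
#' `po_s4_ratio` times basal; the prediction is `1 + (ratio - 1) * p4(t)` with
#' the chain occupancies in closed form. The three rates enter the observable
#' only through `p4`, which is symmetric under their permutation, so they are
#' identifiable only up to ordering (returned sorted decreasing).
#'
#' @param data Data frame with the activation segment, normalized so the
#'   pre-drug level is 1 and time starts at drug onset.
#' @param time,current Column names (tidy-eval); defaults `time_s`, `i_norm`.
#'
#' @return An object of class `threestep_fit`: `k12`, `k23`, `k34` (s^-1,
#'   sorted decreasing), `po_s4_ratio`, `tau_on_star` (s), `sse`, `flagged`.
#' @export
fit_three_step_activation <- function(data, time = time_s, current = i_norm) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ current }})
  if (length(t) < 4) abort("activation segment must have at least 4 samples")
  tt <- t - t[1]

  plateau <- mean(y[tt >= 0.9 * max(tt)])
  ratio0 <- max(plateau, 1.01)
  # median waiting time of a 3-equal-step chain is ~2.67/k
  t_half0 <- tt[which(y >= (y[1] + plateau) / 2)[1]]
  if (is.na(t_half0) || t_half0 <= 0) t_half0 <- max(tt) / 4
  k0 <- 2.674 / t_half0

  obj <- function(lp) {
    k <- exp(lp[1:3]); ratio <- 1 + exp(lp[4])
    pred <- 1 + (ratio - 1) * chain_occupancies(tt, k[1], k[2], k[3])[, "p4"]
    sum((pred - y)^2)
  }
  starts <- list(log(c(k0, k0 * 1.5, k0 / 1.5, ratio0 - 1)),
                 log(c(k0 * 5, k0, k0 / 5, ratio0 - 1)))
  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  k <- sort(exp(best$par[1:3]), decreasing = TRUE)
  ratio <- 1 + exp(best$par[4])
  tau_star <- tryCatch(tau_on_star(tibble(time_s = tt, i_norm = y)),
                       error = function(e) NA_real_)
  structure(
    list(k12 = k[1], k23 = k[2], k34 = k[3], po_s4_ratio = ratio,
         tau_on_star = tau_star, sse = best$value,
         flagged = best$convergence != 0),
    class = "threestep_fit"
  )
}

#' @export
print.threestep_fit <- function(x, ...) {
  cat(sprintf("<threestep_fit> k = %.4g, %.4g, %.4g s^-1; Po(S4)/Po(bas) = %.3f; tau_on* = %.4g s (SSE %.3g)%s\n",
              x$k12, x$k23, x$k34, x$po_s4_ratio, x$tau_on_star, x$sse,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Apparent activation time constant
#'
#' `tau_on* = T_1/2 / ln 2`, where `T_1/2` is the time at which the current
#' first crosses the midpoint between its pre-activated amplitude (the first
#' sample) and its fully activated amplitude (mean of the final 10% of the
#' segment). For a mono-exponential rise this equals the time constant
#' exactly; for sigmoidal rises it summarizes the overall activation delay.
#'
#' @param data Data frame with the activation segment (time from drug onset).
#' @param time,current Column names (tidy-eval); defaults `time_s`, `i_norm`.
#' @return Apparent activation time constant (s).
#' @export
tau_on_star <- function(data, time = time_s, current = i_norm) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ current }})
  tt <- t - t[1]
  tail_sel <- tt >= 0.9 * max(tt)
  plateau <- mean(y[tail_sel])
  if (max(abs(y[tail_sel] - plateau)) > 0.02 * abs(plateau)) {
    abort("no detectable plateau: final 10% of the segment varies by more than 2%")
  }
  mid <- (y[1] + plateau) / 2
  above <- which(y >= mid)
  above <- above[above > 1]
  if (length(above) == 0) abort("current never crosses the activation midpoint")
  i <- above[1]
  # linear interpolation between the bracketing samples
  t_half <- tt[i - 1] + (mid - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
  t_half / log(2)
}
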