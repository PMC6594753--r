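#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per estimated parameter; `glance()` returns a
#' one-row summary of the fit.
#'
#' @param x A fitted object (`ensemble_fit`, `hill_fit`, `cob_fit`,
#'   `decay_fit`, `threestep_fit`, or `calibration_fit`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.ensemble_fit <- function(x, ...) {
  p <- x$params
  est <- c(k_in = p$k_in, k_out = p$k_out, k_on = p$k_on, k_off = p$k_off,
           k_flip = p$k_flip %||% NULL, po_ratio = p$po_ratio, c_t = p$c_t)
  tibble(term = names(est), estimate = unname(est),
         unit = c("s^-1", "s^-1", "M^-1 s^-1", "s^-1",
                  if (!is.null(p$k_flip)) "s^-1", "", "M"))
}

#' @rdname tidiers
#' @export
glance.ensemble_fit <- function(x, ...) {
  tibble(scheme = x$config$scheme, sse = x$sse, converged = x$converged,
         n_evaluations = x$n_evaluations, n_traces = nrow(x$traces),
         k_d_mem = x$derived$k_d_mem, k_half_mem = x$derived$k_half_mem,
         k_half_aq = x$derived$k_half_aq)
}

#' @rdname tidiers
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("k_half", "n_hill", "imax_ratio"),
         estimate = c(x$k_half, x$n_hill, x$imax_ratio),
         unit = c("M", "", ""))
}

#' @rdname tidiers
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(sse = x$sse, n = nrow(x$data))
}

#' @rdname tidiers
#' @export
tidy.cob_fit <- function(x, ...) {
  tibble(term = c("r_co", "r_oc", "r_ob", "r_bo"),
         estimate = c(x$r_co, x$r_oc, x$r_ob, x$r_bo),
         unit = "s^-1")
}

#' @rdname tidiers
#' @export
glance.cob_fit <- function(x, ...) {
  s <- gating_summary(x)
  tibble(loglik = x$loglik, n_open = x$n_open, n_shut = x$n_shut,
         converged = x$converged, tau_b = s$tau_b, tau_ib = s$tau_ib,
         p_open = s$p_open)
}

#' @rdname tidiers
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("tau_off", "a", "b"),
         estimate = c(x$tau_off, x$a, x$b),
         unit = c("s", "", ""))
}

#' @rdname tidiers
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(sse = x$sse, rate_off = x$rate_off, flagged = x$flagged)
}

#' @rdname tidiers
#' @export
tidy.threestep_fit <- function(x, ...) {
  tibble(term = c("k12", "k23", "k34", "po_s4_ratio"),
         estimate = c(x$k12, x$k23, x$k34, x$po_s4_ratio),
         unit = c("s^-1", "s^-1", "s^-1", ""))
}

#' @rdname tidiers
#' @export
glance.threestep_fit <- function(x, ...) {
  tibble(sse = x$sse, tau_on_star = x$tau_on_star, flagged = x$flagged)
}

#' @rdname tidiers
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         unit = c("OD M^-1", "OD"))
}

#' @rdname tidiers
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n)
}
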