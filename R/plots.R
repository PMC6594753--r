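#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of simulated traces,
#' ensemble fits, dose-response fits, and stability plots.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.simulated_trace <- function(object, ...) {
  proto <- attr(object, "protocol")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$i_norm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalized current",
                  title = sprintf("scheme %s", attr(object, "scheme")))
  if (!is.null(proto)) {
    edges <- c(0, cumsum(proto$duration_s))
    drug <- tibble(xmin = edges[-length(edges)], xmax = edges[-1],
                   on = proto$conc_M > 0)
    drug <- drug[drug$on, , drop = FALSE]
    if (nrow(drug) > 0) {
      p <- p + ggplot2::geom_rect(
        data = drug,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.12, fill = "red"
      )
    }
  }
  p
}

#' @rdname plots
#' @export
autoplot.ensemble_fit <- function(object, ...) {
  df <- fitted_traces(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "blue") +
    ggplot2::facet_wrap(~trace_id, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "normalized current",
                  title = sprintf("scheme %d ensemble fit (SSE %.3g)",
                                  object$config$scheme, object$sse))
}

#' @rdname plots
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(conc_M = 10^seq(log10(min(d$conc_M)) - 0.5,
                                 log10(max(d$conc_M)) + 0.5,
                                 length.out = 200))
  k <- object$k_half; n <- object$n_hill; imax <- object$imax_ratio
  grid$stimulation <- (k^n + imax * grid$conc_M^n) / (k^n + grid$conc_M^n)
  ggplot2::ggplot(d, ggplot2::aes(.data$conc_M, .data$stimulation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[drug] (M)", y = "I / I_control",
                  title = sprintf("K_0.5 = %.3g M, n = %.2f, max %.2f-fold",
                                  object$k_half, object$n_hill,
                                  object$imax_ratio))
}

#' Stability plot of windowed open probability
#'
#' Bar plot of open probability over sequential time windows (see
#' [stability_windows()]).
#'
#' @param windows Output of [stability_windows()].
#' @return A ggplot.
#' @export
plot_stability <- function(windows) {
  ggplot2::ggplot(windows,
                  ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                               ymin = 0, ymax = .data$p_open)) +
    ggplot2::geom_rect(fill = "grey60", colour = "grey20") +
    ggplot2::labs(x = "time (s)", y = "open probability")
}
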