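#' Rate-constant set for a drug-partition/binding scheme
#'
#' Bundles the rate constants and open-probability ratio that parameterize one
#' of the four gating schemes, with validation. Units are fixed package-wide:
#' concentrations in M, time in s, `k_on` in M^-1 s^-1.
#'
#' @param k_in Drug entry rate into the membrane per unit cytosolic
#'   concentration (s^-1).
#' @param k_out Membrane exit rate (s^-1).
#' @param k_on Second-order binding rate of membrane-dissolved drug to the
#'   channel (M^-1 s^-1).
#' @param k_off Dissociation rate (s^-1).
#' @param po_ratio Open-probability enhancement `P_o,max / P_o,bas`
#'   (dimensionless, >= 1).
#' @param c_t Total channel binding-site concentration in the target
#'   compartment (M).
#' @param k_flip Inter-leaflet flip rate (s^-1); required by the
#'   two-compartment schemes 2 and 4, must be absent (`NULL`) for schemes 1
#'   and 3.
#'
#' @return An object of class `gating_params` (a named list).
#' @export
#' @examples
#' gating_params(k_in = 4034, k_out = 0.06446, k_on = 870.3,
#'               k_off = 0.007451, po_ratio = 3.935, c_t = 1.66e-6)
gating_params <- function(k_in, k_out, k_on, k_off, po_ratio, c_t,
                          k_flip = NULL) {
  rates <- c(k_in = k_in, k_out = k_out, k_on = k_on, k_off = k_off)
  if (!is.null(k_flip)) rates <- c(rates, k_flip = k_flip)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("all rate constants must be finite and strictly positive")
  }
  if (!is.finite(po_ratio) || po_ratio < 1) {
    abort("`po_ratio` must be >= 1 (potentiation cannot reduce open probability)")
  }
  if (!is.finite(c_t) || c_t <= 0) abort("`c_t` must be > 0")
  structure(
    list(k_in = k_in, k_out = k_out, k_on = k_on, k_off = k_off,
         k_flip = k_flip, po_ratio = po_ratio, c_t = c_t),
    class = "gating_params"
  )
}

#' @export
print.gating_params <- function(x, ...) {
  cat("<gating_params>\n")
  cat(sprintf("  k_in  = %g s^-1   k_out = %g s^-1\n", x$k_in, x$k_out))
  cat(sprintf("  k_on  = %g M^-1 s^-1   k_off = %g s^-1\n", x$k_on, x$k_off))
  if (!is.null(x$k_flip)) cat(sprintf("  k_flip = %g s^-1\n", x$k_flip))
  cat(sprintf("  po_ratio = %g   c_t = %g M\n", x$po_ratio, x$c_t))
  invisible(x)
}

# validate a scheme id; returns integer 1..4
check_scheme <- function(scheme) {
  if (is.character(scheme)) scheme <- as.integer(gsub("[^0-9]", "", scheme))
  scheme <- as.integer(scheme)
  if (length(scheme) != 1 || is.na(scheme) || !scheme %in% 1:4) {
    abort("`scheme` must be one of 1, 2, 3, 4")
  }
  scheme
}

# number of state-vector components per scheme
scheme_dim <- function(scheme) c(2L, 3L, 3L, 4L)[check_scheme(scheme)]

# does the scheme have two binding sites? two membrane compartments?
scheme_two_site <- function(scheme) check_scheme(scheme) %in% c(3L, 4L)
scheme_two_compartment <- function(scheme) check_scheme(scheme) %in% c(2L, 4L)

# check params against a scheme (k_flip presence)
check_params <- function(params, scheme) {
  if (!inherits(params, "gating_params")) {
    abort("`params` must be created with `gating_params()`")
  }
  scheme <- check_scheme(scheme)
  if (scheme_two_compartment(scheme) && is.null(params$k_flip)) {
    abort(sprintf("scheme %d has two membrane compartments and requires `k_flip`",
                  scheme))
  }
  if (!scheme_two_compartment(scheme) && !is.null(params$k_flip)) {
    abort(sprintf("scheme %d has a single membrane compartment; `k_flip` must be NULL",
                  scheme))
  }
  invisible(params)
}

# initial state: drug compartments empty, all channels unliganded.
# (Starting every component at zero would start the normalized current at
# po_ratio rather than 1; see the methods vignette.)
initial_state <- function(scheme, params) {
  scheme <- check_scheme(scheme)
  x0 <- numeric(scheme_dim(scheme))
  # unliganded-channel slot: scheme 1 -> x2, scheme 2 -> x3, scheme 3 -> x2,
  # scheme 4 -> x3
  slot <- c(2L, 3L, 2L, 3L)[scheme]
  x0[slot] <- params$c_t
  x0
}

#' Drug-application protocol
#'
#' A protocol is an ordered sequence of piecewise-constant cytosolic drug
#' concentration segments, stored as a tibble with columns `duration_s` and
#' `conc_M`. Concentrations may be given as multiples of the 1x saturated
#' aqueous solution via `x_saturated`.
#'
#' @param duration_s Segment durations (s), all positive.
#' @param conc_M Cytosolic drug concentration per segment (M, >= 0). Exactly
#'   one of `conc_M` and `x_saturated` must be supplied.
#' @param x_saturated Concentrations as multiples of the saturated solution.
#' @param saturated_conc Calibration of the 1x saturated solution (M); default
#'   62 nM.
#'
#' @return A tibble of class `drug_protocol`.
#' @export
#' @examples
#' # 10 min at 1x saturated drug, then 10 min washout
#' drug_protocol(duration_s = c(600, 600), x_saturated = c(1, 0))
drug_protocol <- function(duration_s, conc_M = NULL, x_saturated = NULL,
                          saturated_conc = .const$saturated_conc) {
  if (is.null(conc_M) == is.null(x_saturated)) {
    abort("supply exactly one of `conc_M` or `x_saturated`")
  }
  if (is.null(conc_M)) conc_M <- x_saturated * saturated_conc
  if (length(duration_s) != length(conc_M)) {
    abort("`duration_s` and the concentration vector must have equal length")
  }
  if (length(duration_s) < 1) abort("a protocol needs at least one segment")
  if (any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    abort("segment durations must be positive")
  }
  if (any(!is.finite(conc_M)) || any(conc_M < 0)) {
    abort("segment concentrations must be non-negative")
  }
  structure(tibble(duration_s = as.numeric(duration_s),
                   conc_M = as.numeric(conc_M)),
            class = c("drug_protocol", "tbl_df", "tbl", "data.frame"))
}

check_protocol <- function(protocol) {
  if (inherits(protocol, "drug_protocol")) return(protocol)
  if (is.data.frame(protocol) &&
      all(c("duration_s", "conc_M") %in% names(protocol))) {
    return(drug_protocol(protocol$duration_s, protocol$conc_M))
  }
  abort("`protocol` must be a `drug_protocol()` or a data frame with columns `duration_s`, `conc_M`")
}
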