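# Reference parameter sets: global-fit averages for the one-compartment
# two-site scheme (3) and the two-compartment two-site scheme (4), with
# C_t for a 100-channel patch in the scheme's default compartment volume.
ref_params <- function(scheme = 3) {
  if (scheme %in% c(1, 3)) {
    gating_params(
      k_in = 62580 * 0.06446, k_out = 0.06446, k_on = 870.3,
      k_off = 0.007451, po_ratio = 3.935,
      c_t = channel_site_concentration(100, 1e-16)
    )
  } else {
    gating_params(
      k_in = 62580 * 0.1565, k_out = 0.1565, k_on = 3703,
      k_off = 0.01075, po_ratio = 3.996, k_flip = 0.04408,
      c_t = channel_site_concentration(100, 5e-17)
    )
  }
}

# standard on/off protocol: 10 min drug, 10 min washout
on_off_protocol <- function(x_sat = 1, on_s = 600, off_s = 600) {
  drug_protocol(c(on_s, off_s), x_saturated = c(x_sat, 0))
}

# two-concentration noiseless ensemble (0.01x and 1x) for a scheme
make_ensemble <- function(scheme, params, out_dt = 1) {
  prots <- list(on_off_protocol(0.01), on_off_protocol(1))
  traces <- lapply(prots, function(pr) {
    tr <- integrate_protocol(scheme, params, pr, out_dt = out_dt)
    tr[, c("time_s", "i_norm")]
  })
  trace_set(traces, prots)
}

# random valid parameter set for any scheme, rates drawn log-uniformly in
# ranges where a 62 nM protocol is informative
random_params <- function(scheme) {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  k_out <- lu(0.03, 0.3)
  gating_params(
    k_in = 62580 * k_out, k_out = k_out,
    k_on = lu(100, 2000), k_off = lu(0.005, 0.05),
    po_ratio = stats::runif(1, 1.5, 6),
    c_t = channel_site_concentration(100,
                                     if (scheme %in% c(2, 4)) 5e-17 else 1e-16),
    k_flip = if (scheme %in% c(2, 4)) lu(0.02, 0.2) else NULL
  )
}
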