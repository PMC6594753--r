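test_that("unliganded drug-free states are fixed points of every scheme", {
  for (scheme in 1:4) {
    p <- if (scheme %in% c(2, 4)) ref_params(4) else ref_params(3)
    x0 <- cftrpot:::initial_state(scheme, p)
    expect_equal(scheme_rhs(scheme, p, x0, v_c = 0),
                 rep(0, length(x0)),
                 info = paste("scheme", scheme))
  }
})

test_that("scheme 3 drug influx matches k_in * V_c from the all-zero drug state", {
  p <- ref_params(3)
  d <- scheme_rhs(3, p, c(0, p$c_t, 0), v_c = 62e-9)
  expect_equal(d[1], 4034 * 62e-9, tolerance = 1e-4)
  expect_equal(d[2], 0)
  expect_equal(d[3], 0)
})

test_that("rhs rejects dimension mismatches and negative states", {
  p <- ref_params(3)
  expect_error(scheme_rhs(3, p, c(0, p$c_t), 0), "length")
  expect_error(scheme_rhs(3, p, c(-1e-9, p$c_t, 0), 0), "non-negative")
  expect_error(scheme_rhs(5, p, c(0, p$c_t, 0), 0), "must be one of")
  p2 <- ref_params(4)
  expect_error(scheme_rhs(3, p2, c(0, p2$c_t, 0), 0), "k_flip")
})

test_that("normalized current interpolates between 1 and po_ratio", {
  p <- ref_params(3)
  expect_equal(normalized_current(3, p, c(0, p$c_t / 2, p$c_t / 2)), 1)
  expect_equal(normalized_current(3, p, c(0, 0, 0)), p$po_ratio)
  # half the channels diliganded
  p2 <- gating_params(k_in = 4034, k_out = 0.06446, k_on = 870.3,
                      k_off = 0.007451, po_ratio = 3.935, c_t = 1e-6)
  expect_equal(normalized_current(3, p2, c(0, 2.5e-7, 2.5e-7)),
               0.5 + 0.5 * 3.935)
})

test_that("steady-state membrane concentrations follow the closed forms", {
  p <- ref_params(3)
  expect_equal(steady_state_concentrations(3, p, 0)$v_m, 0)
  expect_equal(steady_state_concentrations(3, p, 62e-9)$v_m,
               62e-9 * 4034 / (2 * 0.06446), tolerance = 1e-4)
  # fast flip-flop limit: external leaflet approaches the one-compartment form
  p4 <- gating_params(k_in = 62580 * 0.1, k_out = 0.1, k_on = 1000,
                      k_off = 0.01, po_ratio = 4, k_flip = 1e4,
                      c_t = 1e-6)
  ss <- steady_state_concentrations(4, p4, 62e-9)
  expect_equal(ss$v_me, 62e-9 * 62580 / 2, tolerance = 1e-4)
  expect_equal(ss$v_mc, 62e-9 * 62580 / 2, tolerance = 1e-4)
})

test_that("steady-state response has the right limits, midpoint, and monotonicity", {
  p <- ref_params(3)
  expect_equal(steady_state_response(3, p, 0), 1)
  # V_m = K_d: two-site occupancy is 1/4
  kd <- p$k_off / p$k_on
  v_c_mid <- kd / (p$k_in / (2 * p$k_out))
  expect_equal(steady_state_response(3, p, v_c_mid),
               1 + (p$po_ratio - 1) * 0.25, tolerance = 1e-12)
  # saturated stimulation with the reference parameters is ~3.9-fold
  expect_equal(steady_state_response(3, p, 62e-9), 3.909, tolerance = 1e-3)
  grid <- 10^seq(-13, -7, length.out = 50)
  resp <- steady_state_response(3, p, grid)
  expect_true(all(diff(resp) >= 0))
  expect_lt(max(resp), p$po_ratio)
})

test_that("derived affinities reproduce the printed closed forms", {
  p <- gating_params(k_in = 62580 * 0.1, k_out = 0.1, k_on = 1000,
                     k_off = 0.01, po_ratio = 4, c_t = 1e-6)
  d1 <- derived_affinities(1, p)
  expect_equal(d1$k_d_mem, 1e-5)
  expect_equal(d1$k_half_mem, d1$k_d_mem) # single-site identity
  d3 <- derived_affinities(3, p)
  expect_equal(d3$k_half_mem, (1 + sqrt(2)) * 1e-5)
  # reference parameter set: apparent aqueous affinity ~0.66 nM
  d <- derived_affinities(3, ref_params(3))
  expect_equal(d$k_half_aq,
               (1 + sqrt(2)) * (0.007451 / 870.3) / (4034 / (2 * 0.06446)),
               tolerance = 1e-6)
  expect_equal(d$k_half_aq, 0.66e-9, tolerance = 0.01)
})

test_that("midpoint Hill slope is 1 for single-site and 2(2-sqrt(2)) for two-site schemes", {
  expect_equal(midpoint_hill_slope(1), 1)
  expect_equal(midpoint_hill_slope(2), 1)
  expect_equal(midpoint_hill_slope(3), 2 * (2 - sqrt(2)))
  expect_equal(midpoint_hill_slope(4), midpoint_hill_slope(3))
  # agreement with the numerically evaluated logit slope at the midpoint
  for (scheme in c(1, 3)) {
    p <- ref_params(3)
    frac <- function(v_c) {
      (steady_state_response(scheme, p, v_c) - 1) / (p$po_ratio - 1)
    }
    v_mid <- uniroot(function(lv) frac(exp(lv)) - 0.5,
                     c(log(1e-14), log(1e-5)), tol = 1e-12)$root
    h <- 1e-4
    logit <- function(lv) { f <- frac(exp(lv)); log(f / (1 - f)) }
    slope <- (logit(v_mid + h) - logit(v_mid - h)) / (2 * h)
    expect_equal(slope, midpoint_hill_slope(scheme), tolerance = 1e-3)
  }
})

test_that("drug-free protocols leave the normalized current at exactly 1", {
  p <- ref_params(3)
  tr <- integrate_protocol(3, p, drug_protocol(c(100, 100), conc_M = c(0, 0)),
                           out_dt = 1)
  expect_true(all(tr$i_norm == 1))
  expect_equal(tr$i_norm[1], 1) # initialization convention
})

test_that("long integrations converge to the closed-form steady state for all schemes", {
  withr::with_seed(11, {
    for (scheme in 1:4) {
      for (rep in 1:2) {
        p <- random_params(scheme)
        t_end <- 50 / min(p$k_out, p$k_off)
        tr <- integrate_protocol(scheme, p,
                                 drug_protocol(t_end, conc_M = 62e-9),
                                 out_dt = t_end / 50)
        expect_equal(tail(tr$i_norm, 1),
                     steady_state_response(scheme, p, 62e-9),
                     tolerance = 1e-4, info = paste("scheme", scheme))
        # drug compartment(s) against the closed forms
        xs <- attr(tr, "final_state")
        ss <- steady_state_concentrations(scheme, p, 62e-9)
        if (scheme %in% c(1, 3)) {
          expect_equal(xs[1], ss$v_m, tolerance = 1e-4)
        } else {
          expect_equal(xs[1], ss$v_mc, tolerance = 1e-4)
          expect_equal(xs[2], ss$v_me, tolerance = 1e-4)
        }
      }
    }
  })
})

test_that("channel mass is conserved and states stay physical along trajectories", {
  p <- ref_params(3)
  tr <- integrate_protocol(3, p, on_off_protocol(1), out_dt = 1)
  st <- attr(tr, "states")
  expect_true(all(st >= -1e-9 * p$c_t))
  occupied <- st[, 2] + st[, 3]
  expect_true(all(occupied <= p$c_t * (1 + 1e-9)))
  # diliganded fraction implied non-negative
  expect_true(all(p$c_t - occupied >= -1e-9 * p$c_t))
})

test_that("halving the integration step changes the trace by less than 1e-4 relative", {
  p <- ref_params(3)
  prot <- on_off_protocol(1)
  a <- integrate_protocol(3, p, prot, dt = 0.02, out_dt = 2)
  b <- integrate_protocol(3, p, prot, dt = 0.01, out_dt = 2)
  common <- intersect(a$time_s, b$time_s)
  ia <- a$i_norm[match(common, a$time_s)]
  ib <- b$i_norm[match(common, b$time_s)]
  expect_lt(max(abs(ia - ib) / ib), 1e-4)
})

test_that("the current washes back to 1 after drug removal", {
  p <- ref_params(3)
  t_off <- 50 / p$k_off
  tr <- integrate_protocol(3, p, drug_protocol(c(600, t_off),
                                               x_saturated = c(1, 0)),
                           out_dt = 10)
  expect_equal(tail(tr$i_norm, 1), 1, tolerance = 1e-3)
})

test_that("terminal on-current matches the closed-form steady state with reference parameters", {
  p <- ref_params(3)
  tr <- integrate_protocol(3, p, drug_protocol(600, conc_M = 62e-9),
                           out_dt = 10)
  expect_equal(tail(tr$i_norm, 1), steady_state_response(3, p, 62e-9),
               tolerance = 1e-4)
})
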