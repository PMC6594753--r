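test_that("the Gaussian filter has unit DC gain and -3 dB attenuation at the corner", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  const <- tibble::tibble(time_s = t, current = rep(2.5, length(t)))
  expect_equal(gaussian_filter(const, 50)$current, const$current,
               tolerance = 1e-12)
  # impulse response sums to 1 (DC gain)
  imp <- tibble::tibble(time_s = t,
                        current = c(rep(0, 1000), 1, rep(0, length(t) - 1001)))
  expect_equal(sum(gaussian_filter(imp, 50)$current), 1, tolerance = 1e-9)
  # sine at the corner frequency attenuated to 1/sqrt(2) +- 5%
  sine <- tibble::tibble(time_s = t, current = sin(2 * pi * 50 * t))
  filtered <- gaussian_filter(sine, 50)
  mid <- filtered$current[t > 0.5 & t < 1.5]
  expect_equal(max(abs(mid)), 1 / sqrt(2), tolerance = 0.05)
  expect_error(gaussian_filter(sine, 600), "Nyquist")
})

test_that("idealization recovers noiseless rectangular gating exactly", {
  dt <- 1e-3
  lv <- rep(c(0L, 1L, 0L, 1L, 0L), times = c(1000, 500, 2000, 300, 1200))
  d <- tibble::tibble(time_s = seq_along(lv) * dt, current = lv * 0.4)
  ev <- idealize(d, unitary_current = 0.4, n_channels = 1, dead_time = 6e-3)
  expect_equal(ev$level, c(0L, 1L, 0L, 1L, 0L))
  expect_equal(ev$duration_s, c(1, 0.5, 2, 0.3, 1.2), tolerance = 1e-9)

  zero <- tibble::tibble(time_s = seq(0, 1, dt), current = rep(0, 1001))
  ev0 <- idealize(zero, 0.4, 1)
  expect_equal(nrow(ev0), 1L)
  expect_equal(ev0$level, 0L)
})

test_that("sub-dead-time events are concatenated into the preceding event", {
  m <- cftrpot:::apply_dead_time(c(0L, 1L, 0L, 1L), c(1, 0.004, 0.5, 0.2),
                                 dead_time = 0.006)
  expect_equal(m$level, c(0L, 1L))
  expect_equal(m$duration, c(1.504, 0.2))
  expect_true(all(m$duration >= 0.006))
})

test_that("open probability is the level-weighted time average and is reversal-invariant", {
  ev <- cftrpot:::new_event_list(c(1L, 0L), c(5, 5), 0, 1L)
  expect_equal(open_probability(ev), 0.5)
  ev2 <- cftrpot:::new_event_list(c(2L, 2L), c(1, 3), 0, 2L)
  expect_equal(open_probability(ev2), 1)
  ev3 <- sim_cob_events(0.3, 1, 10, 100, duration = 200, seed = 2)
  ev3_rev <- cftrpot:::new_event_list(rev(ev3$level), rev(ev3$duration_s),
                                      attr(ev3, "dead_time"), 1L)
  expect_equal(open_probability(ev3), open_probability(ev3_rev))
})

test_that("simulated C-O-B records reproduce the stationary open probability", {
  r <- c(r_co = 0.84, r_oc = 1.0, r_ob = 10, r_bo = 100)
  # independent linear-algebra oracle: null space of the generator matrix
  Q <- rbind(c(-r["r_co"], r["r_co"], 0),
             c(r["r_oc"], -(r["r_oc"] + r["r_ob"]), r["r_ob"]),
             c(0, r["r_bo"], -r["r_bo"]))
  pi_lin <- solve(t(cbind(Q, 1) %*% t(cbind(Q, 1))),
                  as.numeric(cbind(Q, 1) %*% c(0, 0, 0, 1)))
  ev <- sim_cob_events(r[1], r[2], r[3], r[4], duration = 2000, seed = 9,
                       dead_time = 0)
  expect_equal(open_probability(ev), pi_lin[2], tolerance = 0.03)
})

test_that("burst_summary matches the printed formulas and the stationary oracle", {
  s <- burst_summary(r_co = 0.5, r_oc = 1, r_ob = 0, r_bo = 100)
  expect_equal(s$tau_b, 1)       # no flicker: burst = open dwell
  expect_equal(s$tau_ib, 2)      # 1 / r_CO
  s2 <- burst_summary(0.84, 0.82, 18, 110)
  expect_equal(s2$tau_b, (1 / 0.82) * (1 + 18 / 110))
  # stationary p_open against an independent linear-algebra computation
  withr::with_seed(21, {
    for (i in 1:10) {
      r <- exp(runif(4, log(0.1), log(100)))
      Q <- rbind(c(-r[1], r[1], 0),
                 c(r[2], -(r[2] + r[3]), r[3]),
                 c(0, r[4], -r[4]))
      M <- cbind(Q, 1)
      pi_lin <- solve(M %*% t(M), as.numeric(M %*% c(0, 0, 0, 1)))
      expect_equal(burst_summary(r[1], r[2], r[3], r[4])$p_open, pi_lin[2],
                   tolerance = 1e-10)
    }
  })
})

test_that("empirical burst durations match the burst-duration formula", {
  ev <- sim_cob_events(0.84, 0.82, 18, 110, duration = 3000, seed = 42)
  b <- burst_durations(ev, t_crit = 0.1)
  expect_equal(mean(b), burst_summary(0.84, 0.82, 18, 110)$tau_b,
               tolerance = 0.1)
})

test_that("stability windows chop the record into 46-s open-probability estimates", {
  ev <- cftrpot:::new_event_list(c(1L, 0L), c(50, 50), 0, 1L)
  w <- stability_windows(ev, window = 46)
  expect_equal(nrow(w), 2L)
  expect_equal(w$p_open[1], 1)              # first 46 s fully open
  expect_equal(w$p_open[2], 4 / 46)         # 4 s open, 42 s shut
  # a homogeneous record has roughly constant windows
  ev2 <- sim_cob_events(0.5, 1, 10, 100, duration = 460, seed = 3)
  w2 <- stability_windows(ev2)
  expect_equal(nrow(w2), 10L)
  expect_lt(max(abs(w2$p_open - open_probability(ev2))), 0.25)
  expect_error(stability_windows(cftrpot:::new_event_list(1L, 10, 0, 1L)),
               "shorter")
})

test_that("C-O-B rates are recovered within 15% from a long simulated record", {
  true <- c(0.84, 0.82, 18, 110)
  ev <- sim_cob_events(true[1], true[2], true[3], true[4],
                       duration = 3000, seed = 42)
  fit <- fit_cob(ev)
  est <- c(fit$r_co, fit$r_oc, fit$r_ob, fit$r_bo)
  expect_true(all(abs(est - true) / true < 0.15))
  expect_true(fit$converged)
})

test_that("a record without flicker yields a C-O-B fit with negligible blocking rate", {
  ev <- sim_cob_events(0.2, 1, 0, 100, duration = 1500, seed = 7)
  fit <- fit_cob(ev)
  expect_lt(fit$r_ob / fit$r_oc, 0.02)
  expect_equal(fit$r_co, 0.2, tolerance = 0.15)
  expect_equal(fit$r_oc, 1, tolerance = 0.15)
})

test_that("longer records reduce the C-O-B recovery error", {
  # short records are variance-dominated; long ones approach the small bias
  # floor of the first-order dead-time correction (see vignette)
  true <- c(0.84, 0.82, 18, 110)
  err <- sapply(c(150, 2400), function(dur) {
    errs <- sapply(1:4, function(seed) {
      fit <- fit_cob(sim_cob_events(true[1], true[2], true[3], true[4],
                                    duration = dur, seed = seed))
      max(abs(c(fit$r_co, fit$r_oc, fit$r_ob, fit$r_bo) - true) / true)
    })
    mean(errs)
  })
  expect_lt(err[2], err[1])
})

test_that("idealizing a filtered noisy simulation preserves the record's open probability", {
  r <- c(0.2, 1, 0, 100) # dwells well above the dead time
  # same seed, with and without noise: identical gating realizations
  tr_clean <- sim_single_channel_trace(r[1], r[2], r[3], r[4], n_channels = 1,
                                       duration = 400, sampling_rate = 500,
                                       unitary_current = 1, noise_sd = 0,
                                       seed = 3)
  tr_noisy <- sim_single_channel_trace(r[1], r[2], r[3], r[4], n_channels = 1,
                                       duration = 400, sampling_rate = 500,
                                       unitary_current = 1, noise_sd = 0.15,
                                       seed = 3)
  p_true <- mean(tr_clean$current) # exact open fraction of this realization
  ev <- idealize(gaussian_filter(tr_noisy, corner = 50), unitary_current = 1,
                 n_channels = 1)
  expect_equal(open_probability(ev), p_true, tolerance = 0.05)
})

test_that("a basal parameterization near P_o 0.16 and its potentiated twin differ ~4-fold", {
  # basal: opening slow, closing fast; potentiated: opening x4, closing /2.5
  bas <- c(r_co = 0.2, r_oc = 1.0, r_ob = 18, r_bo = 110)
  pot <- c(r_co = 0.8, r_oc = 0.4, r_ob = 18, r_bo = 110)
  expect_equal(burst_summary(bas[1], bas[2], bas[3], bas[4])$p_open, 0.16,
               tolerance = 0.05)
  ev_b <- sim_cob_events(bas[1], bas[2], bas[3], bas[4], 1500, seed = 1)
  ev_p <- sim_cob_events(pot[1], pot[2], pot[3], pot[4], 1500, seed = 2)
  ratio <- open_probability(ev_p) / open_probability(ev_b)
  expect_equal(ratio,
               burst_summary(pot[1], pot[2], pot[3], pot[4])$p_open /
                 burst_summary(bas[1], bas[2], bas[3], bas[4])$p_open,
               tolerance = 0.15)
})

test_that("multi-channel records are refused by the rate fitter but not by P_o analyses", {
  tr <- sim_single_channel_trace(0.3, 1, 0, 100, n_channels = 3,
                                 duration = 120, sampling_rate = 200,
                                 unitary_current = 1, noise_sd = 0, seed = 4)
  ev <- idealize(tr, 1, n_channels = 3)
  expect_true(max(ev$level) <= 3)
  expect_gt(open_probability(ev), 0)
  expect_error(fit_cob(ev), "single-channel")
})
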