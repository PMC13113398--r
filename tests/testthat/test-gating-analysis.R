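test_that("peak extraction honours polarity, blanking and degenerate input", {
  tr <- tibble::tibble(
    cell_id = "c", condition = "x", sweep = 1L, command = -20,
    epoch = "step",
    t_ms = seq(0, 5, by = 0.1),
    value = -2 * exp(-((seq(0, 5, by = 0.1) - 1.3) / 0.4)^2)
  )
  sw <- navclamp:::new_sweep_set(tr, "current", "uA", NULL, 1L)
  pk <- extract_peaks(sw, blank_ms = 0.2)
  expect_equal(pk$peak, -2, tolerance = 1e-6)
  expect_equal(pk$t_peak_ms, 1.3)
  # all-zero trace: peak 0 with the flat flag and a warning
  tr0 <- tr
  tr0$value <- 0
  sw0 <- navclamp:::new_sweep_set(tr0, "current", "uA", NULL, 1L)
  expect_warning(pk0 <- extract_peaks(sw0), "flat")
  expect_equal(pk0$peak, 0)
  expect_true(pk0$flat)
})

test_that("conductance transform divides by driving force and guards vrev", {
  iv <- tibble::tibble(step_mV = c(-20, 60, 30), peak = c(-2, 0.01, -1.5))
  g <- conductance(iv, vrev = 60)
  expect_equal(g$g[g$step_mV == -20], -2 / (-80))
  expect_true(g$excluded[g$step_mV == 60])
  expect_false(g$excluded[g$step_mV == 30])
  expect_error(conductance(iv[2, ], vrev = 60), "vrev")
})

test_that("reversal potential comes from the zero crossing, else the I-V fit", {
  iv <- tibble::tibble(step_mV = c(0, 20, 40, 45),
                       peak = c(-2, -1, -0.2, 0.2))
  vr <- estimate_vrev(iv)
  expect_equal(as.numeric(vr), 42.5)
  expect_equal(attr(vr, "source"), "zero-crossing")
  # no sign change: falls back to the full Boltzmann I-V fit
  p <- oracle_params()
  proto <- protocol_spec("IV_STEP", holding_mV = -90, step_start_mV = -80,
                         step_stop_mV = 30, step_increment_mV = 5,
                         step_duration_ms = 50)
  iv2 <- extract_peaks(simulate_iv(p, proto, noise_sd = 0, seed = 1),
                       blank_ms = 0)
  vr2 <- estimate_vrev(iv2)
  expect_equal(attr(vr2, "source"), "fit-derived")
  expect_equal(as.numeric(vr2), p$vrev, tolerance = 0.5)
})

test_that("activation fit is exact on exact Boltzmann samples", {
  v <- seq(-60, 20, by = 5)
  g <- tibble::tibble(step_mV = v, g = 1 / (1 + exp(-(v + 25) / 5)),
                      excluded = FALSE)
  f <- fit_activation(g)
  expect_true(f$converged)
  expect_equal(f$vhalf, -25, tolerance = 1e-6)
  expect_equal(f$k, 5, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(max(abs(f$data$po - g$g)), 0, tolerance = 1e-6)
})

test_that("activation fit refuses a monotone-decreasing curve", {
  v <- seq(-60, 20, by = 5)
  g <- tibble::tibble(step_mV = v, g = 1 / (1 + exp((v + 25) / 5)),
                      excluded = FALSE)
  f <- fit_activation(g)
  expect_false(f$converged)
  expect_true(is.na(f$vhalf))
})

test_that("activation fit recovers parameters under noise (calibration)", {
  v <- seq(-60, 20, by = 5)
  truth <- 1 / (1 + exp(-(v + 25) / 5))
  set.seed(42)
  errs <- t(replicate(20, {
    g <- tibble::tibble(step_mV = v, g = truth + rnorm(length(v), sd = 0.02),
                        excluded = FALSE)
    f <- fit_activation(g)
    c(f$vhalf + 25, f$k - 5)
  }))
  expect_lte(mean(abs(errs[, 1])), 0.5)
  expect_lte(mean(abs(errs[, 2])), 0.3)
})

test_that("inactivation fit recovers midpoint, floor, and direction guard", {
  v <- seq(-80, 0, by = 5)
  y <- 1 / (1 + exp((v + 45) / 6))
  f <- fit_inactivation(tibble::tibble(step_mV = v, peak = y))
  expect_equal(f$vhalf, -45, tolerance = 1e-6)
  expect_equal(f$k, 6, tolerance = 1e-6)
  # floor-enabled fit recovers a 10 % availability pedestal
  y2 <- 0.1 + 0.9 / (1 + exp((v + 45) / 6))
  f2 <- fit_inactivation(tibble::tibble(step_mV = v, peak = y2),
                         floor = TRUE)
  expect_equal(f2$floor, 0.1, tolerance = 0.02)
  # increasing input cannot be an inactivation curve
  f3 <- fit_inactivation(tibble::tibble(step_mV = v, peak = rev(y)))
  expect_false(f3$converged)
})

test_that("short prepulses bias the fitted inactivation midpoint positive", {
  p <- gating_params()
  short <- protocol_spec("SSI_TWO_STEP", holding_mV = -50,
                         step_start_mV = -60, step_stop_mV = 60,
                         step_increment_mV = 10, prepulse_duration_ms = 3,
                         test_pulse_mV = -20, step_duration_ms = 200)
  f_short <- analyze_ssi(simulate_ssi(p, short, noise_sd = 0, seed = 1))$fit
  f_long <- analyze_ssi(simulate_ssi(p, protocol_preset("helix_ssi"),
                                     noise_sd = 0, seed = 1))$fit
  expect_gt(f_short$vhalf, f_long$vhalf + 2)
})

test_that("the full Boltzmann I-V fit recovers Gmax, Vrev, and its identity", {
  p <- oracle_params(gmax = 100)
  sw <- simulate_iv(p, protocol_preset("oocyte_iv"), noise_sd = 0, seed = 1)
  f <- fit_iv_gmax(extract_peaks(sw, blank_ms = 0, polarity = "absolute"))
  expect_true(f$converged)
  expect_equal(f$vrev, p$vrev, tolerance = 0.5)
  # availability at -90 mV holding is ~1, so fitted Gmax ~ generative
  expect_equal(f$gmax, 100 * steady_state_gates(p, -90)$h_inf,
               tolerance = 0.01)
  # algebraic identity k_equiv = RT/(zact F)
  expect_equal(f$k_equiv_mV, 1000 * 8.314 * f$temperature_K /
                 (f$zact * 96485), tolerance = 1e-12)
})

test_that("fitted Gmax ratio recovers a generative 50 % conductance drop", {
  p <- gating_params(gmax = 100)
  pt <- apply_toxin(p, toxin_effect("venom", scale_gmax = 0.5))
  proto <- protocol_preset("oocyte_iv")
  f1 <- fit_iv_gmax(extract_amplitudes(
    simulate_iv(p, proto, noise_sd = 0.01, seed = 3)))
  f2 <- fit_iv_gmax(extract_amplitudes(
    simulate_iv(pt, proto, noise_sd = 0.01, seed = 4)))
  expect_equal(f2$gmax / f1$gmax, 0.5, tolerance = 0.04)
})

test_that("window area matches the symmetric closed form and refines stably", {
  a <- fit_boltzmann_exact(-30, 5, "activation")
  b <- fit_boltzmann_exact(-30, 5, "inactivation")
  w <- window_area(a, b, v_lo = -130, v_hi = 70, dv = 0.1)
  # symmetric pair: 2 k ln 2, in percent x mV
  expect_equal(w$area, 2 * 5 * log(2) * 100, tolerance = 1e-3)
  expect_equal(w$crossing_mV, -30)
  w2 <- window_area(a, b, v_lo = -130, v_hi = 70, dv = 0.05)
  expect_lt(abs(w2$area / w$area - 1), 1e-3)
  # disjoint curves leave almost no window
  far <- window_area(fit_boltzmann_exact(-10, 5, "activation"),
                     fit_boltzmann_exact(-80, 5, "inactivation"),
                     v_lo = -130, v_hi = 70)
  expect_lt(far$area, 1)
  # unconverged inputs are rejected
  bad <- fit_boltzmann_exact(-30, 5, "activation")
  bad$converged <- FALSE
  expect_error(window_area(bad, b), "converged")
})

test_that("analysis round trip on noise-free data recovers generative gating", {
  p <- oracle_params()
  iv <- analyze_iv(simulate_iv(p, protocol_preset("helix_iv"),
                               noise_sd = 0, seed = 1))
  expect_equal(iv$fit$vhalf, p$act_vhalf, tolerance = 1e-3)
  expect_equal(iv$fit$k, p$act_k, tolerance = 1e-3)
  # fitted amplitude matches the maximal conductance (availability-scaled)
  h0 <- steady_state_gates(p, -50)$h_inf
  expect_equal(iv$fit$amplitude, p$gmax * h0, tolerance = 0.02 * p$gmax)
  ssi <- analyze_ssi(simulate_ssi(p, protocol_preset("helix_ssi"),
                                  noise_sd = 0, seed = 1))
  expect_equal(ssi$fit$vhalf, p$inact_vhalf, tolerance = 1e-2)
  expect_equal(ssi$fit$k, p$inact_k, tolerance = 1e-2)
})

test_that("tidy and glance expose fit parameters as tibbles", {
  f <- fit_boltzmann_exact(-25, 5, "activation")
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "vhalf"], -25)
  gl <- glance(f)
  expect_true(gl$converged)
  p <- oracle_params(gmax = 50)
  gf <- fit_iv_gmax(extract_peaks(
    simulate_iv(p, protocol_preset("oocyte_iv"), noise_sd = 0, seed = 1),
    blank_ms = 0, polarity = "absolute"))
  expect_equal(tidy(gf)$term,
               c("gmax", "vrev", "vhalf", "zact", "k_equiv_mV"))
  expect_s3_class(glance(gf), "tbl_df")
})
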