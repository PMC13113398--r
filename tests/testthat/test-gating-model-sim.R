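test_that("steady-state gates evaluate the Boltzmann forms and are monotone", {
  p <- gating_params(act_vhalf = -25, act_k = 5, inact_vhalf = -45)
  # midpoint symmetry
  expect_equal(steady_state_gates(p, -25)$m_inf, 0.5)
  # direct scalar evaluation oracle: v = vhalf + 2k
  expect_equal(steady_state_gates(p, -15)$m_inf, 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # saturation limit of the inactivation gate
  expect_lt(steady_state_gates(p, -45 + 10 * p$inact_k)$h_inf, 1e-4)
  # strict monotonicity over a fine grid
  g <- steady_state_gates(p, seq(-100, 60, by = 0.5))
  expect_true(all(diff(g$m_inf) > 0))
  expect_true(all(diff(g$h_inf) < 0))
})

test_that("toxin effects compose arithmetically and are re-validated", {
  p <- gating_params(act_vhalf = -30)
  id <- toxin_effect("null")
  expect_equal(apply_toxin(p, id), p)
  # the printed Tch3 activation displacement forces the arithmetic
  shifted <- apply_toxin(p, toxin_effect("Tch3", d_act_vhalf = 3.94))
  expect_equal(shifted$act_vhalf, -26.06)
  # scale composition
  half <- toxin_effect("v", scale_gmax = 0.5)
  expect_equal(apply_toxin(apply_toxin(p, half), half)$gmax, p$gmax / 4)
  # invariant violations are named rejections
  expect_error(apply_toxin(p, toxin_effect("bad", scale_gmax = 0)), "gmax")
  expect_error(apply_toxin(p, toxin_effect("bad", d_persistent_frac = 1.5)),
               "persistent_frac")
})

test_that("protocol presets match the recording configurations", {
  oiv <- protocol_preset("oocyte_iv")
  expect_equal(oiv$holding_mV, -90)
  expect_equal(navclamp:::step_voltages(oiv), seq(-80, 65, by = 5))
  expect_equal(oiv$step_duration_ms, 50)
  hssi <- protocol_preset("helix_ssi")
  expect_equal(hssi$test_pulse_mV, -20)
  expect_equal(hssi$prepulse_duration_ms, 200)
  hrec <- protocol_preset("helix_recovery")
  expect_equal(hrec$interpulse_ms, seq(5, 80, by = 5))
  hcc <- protocol_preset("helix_cc")
  expect_equal(hcc$stim_amplitudes_nA, c(0.5, 1.0, 1.5))
  expect_equal(hcc$stim_duration_ms, 500)
  expect_error(protocol_spec("IV_STEP", holding_mV = -90, step_start_mV = -80,
                             step_stop_mV = 63, step_increment_mV = 5,
                             step_duration_ms = 50),
               "divide")
})

test_that("simulation is deterministic and zero at the reversal potential", {
  p <- gating_params()
  a <- simulate_iv(p, protocol_preset("helix_iv"), noise_sd = 0.02, seed = 7)
  b <- simulate_iv(p, protocol_preset("helix_iv"), noise_sd = 0.02, seed = 7)
  expect_identical(a$value, b$value)
  c_ <- simulate_iv(p, protocol_preset("helix_iv"), noise_sd = 0.02, seed = 8)
  expect_false(identical(a$value, c_$value))
  # driving-force zero: the step at V = vrev carries exactly no current
  nf <- simulate_iv(p, protocol_preset("helix_iv"), noise_sd = 0, seed = 1)
  at_rev <- nf$value[nf$command == p$vrev & nf$epoch == "step"]
  expect_true(all(at_rev == 0))
  expect_error(simulate_iv(p, protocol_preset("helix_iv"), noise_sd = -1),
               "noise_sd")
  expect_error(simulate_iv(p, protocol_preset("helix_ssi")), "IV_STEP")
})

test_that("noise-free instantaneous-activation peaks match the closed form", {
  p <- oracle_params(persistent_frac = 0)
  proto <- protocol_preset("oocyte_iv")
  sw <- simulate_iv(p, proto, noise_sd = 0, seed = 1)
  iv <- extract_peaks(sw, blank_ms = 0, polarity = "absolute")
  gg <- steady_state_gates(p, iv$step_mV)
  h0 <- steady_state_gates(p, proto$holding_mV)$h_inf
  closed <- p$gmax * (iv$step_mV - p$vrev) * gg$m_inf * h0
  nz <- abs(closed) > 1e-12
  expect_equal(iv$peak[nz], closed[nz], tolerance = 1e-6)
})

test_that("persistent fraction floors the late current", {
  p <- oracle_params(persistent_frac = 0.1)
  proto <- protocol_preset("helix_iv")
  sw <- simulate_iv(p, proto, noise_sd = 0, seed = 1)
  d <- dplyr::filter(sw, command == 0, epoch == "step")
  onset <- d$value[1]
  late <- mean(d$value[d$t_ms > max(d$t_ms) - 10])
  h0 <- steady_state_gates(p, proto$holding_mV)$h_inf
  hinf <- steady_state_gates(p, 0)$h_inf
  # late/onset -> (pf + (1-pf) h_inf) / (pf + (1-pf) h0)
  expect_equal(late / onset,
               (0.1 + 0.9 * hinf) / (0.1 + 0.9 * h0), tolerance = 1e-3)
})

test_that("SSI availability follows first-order relaxation in the prepulse", {
  # finite prepulse: availability = h_inf + (h0 - h_inf) exp(-d / tau)
  # prepulse at -25 mV sits in the inactivating regime (h_inf < 0.5), so
  # relaxation runs on the fast decay tau (slow fraction 0 here)
  p <- oracle_params()
  h0 <- steady_state_gates(p, -90)$h_inf
  for (dur in c(2, 5, 20)) {
    proto <- protocol_spec("SSI_TWO_STEP", holding_mV = -90,
                           step_start_mV = -25, step_stop_mV = -25,
                           step_increment_mV = 5, prepulse_duration_ms = dur,
                           test_pulse_mV = 0, step_duration_ms = 50)
    sw <- simulate_ssi(p, proto, noise_sd = 0, seed = 1)
    pk <- extract_peaks(sw, epoch = "test", blank_ms = 0)
    hinf <- steady_state_gates(p, -25)$h_inf
    expected <- hinf + (h0 - hinf) * exp(-dur / p$tau_inact_fast)
    base <- extract_peaks(
      simulate_ssi(p, protocol_spec("SSI_TWO_STEP", holding_mV = -90,
                                    step_start_mV = -120, step_stop_mV = -120,
                                    step_increment_mV = 5,
                                    prepulse_duration_ms = 200,
                                    test_pulse_mV = 0, step_duration_ms = 50),
                   noise_sd = 0, seed = 1),
      epoch = "test", blank_ms = 0)
    expect_equal(pk$peak / base$peak, expected, tolerance = 5e-3)
  }
})

test_that("full availability and midpoint prepulses scale the test peak", {
  p <- oracle_params()
  proto <- protocol_preset("oocyte_ssi")
  sw <- simulate_ssi(p, proto, noise_sd = 0, seed = 1)
  pk <- extract_peaks(sw, epoch = "test", blank_ms = 0)
  # hyperpolarized prepulse (h_inf ~ 1) matches the no-prepulse peak
  p_hyp <- pk$peak[pk$step_mV == -80]
  iv <- extract_peaks(simulate_iv(p, protocol_preset("oocyte_iv"),
                                  noise_sd = 0, seed = 1), blank_ms = 0)
  expect_equal(p_hyp, iv$peak[iv$step_mV == 0], tolerance = 2e-3)
  # prepulse at the inactivation midpoint halves the maximal test peak
  p_mid <- pk$peak[pk$step_mV == p$inact_vhalf]
  expect_equal(p_mid / max(abs(pk$peak)) * sign(p_mid) * -1, -0.5,
               tolerance = 0.01)
})

test_that("recovery ratio relaxes toward one and is monotone", {
  p <- recovery_oracle_params(recovery_tau = 10)
  sw <- simulate_recovery(p, protocol_preset("helix_recovery"),
                          noise_sd = 0, seed = 1)
  rc <- recovery_fractions(sw)
  expect_true(all(diff(rc$fraction) > 0))
  expect_gt(rc$fraction[rc$interpulse_ms == 80], 0.999)
  th <- 1 - exp(-rc$interpulse_ms / 10)
  expect_equal(rc$fraction, th, tolerance = 0.01)
})

test_that("peak curves converge under sample-grid refinement", {
  p <- gating_params()
  proto <- protocol_preset("helix_iv")
  proto_fine <- proto
  proto_fine$sample_rate_kHz <- 40
  pk1 <- extract_peaks(simulate_iv(p, proto, noise_sd = 0, seed = 1))
  pk2 <- extract_peaks(simulate_iv(p, proto_fine, noise_sd = 0, seed = 1))
  nz <- abs(pk1$peak) > 1e-9
  expect_lt(max(abs(pk2$peak[nz] / pk1$peak[nz] - 1)), 1e-3)
})

test_that("the fixture neuron rests stably, fires reproducibly, and needs sodium", {
  n <- neuron_params()
  zero <- protocol_spec("CURRENT_CLAMP_STEPS", holding_mV = NA,
                        stim_amplitudes_nA = 0, stim_duration_ms = 1000,
                        sample_rate_kHz = 10, baseline_ms = 50)
  v <- simulate_current_clamp(n, zero, seed = 1)$value
  settled <- v[-seq_len(1000)]
  expect_lt(max(settled) - min(settled), 1)  # < 1 mV drift over ~1 s
  # spike-count determinism across runs
  r1 <- analyze_excitability(simulate_current_clamp(n, seed = 1))
  r2 <- analyze_excitability(simulate_current_clamp(n, seed = 1))
  expect_identical(r1$n_spikes, r2$n_spikes)
  expect_true(all(r1$n_spikes > 0))
  # no regenerative spike without the sodium conductance
  passive <- neuron_params(sodium = gating_params(gmax = 1e-9, vrev = 55))
  rp <- analyze_excitability(simulate_current_clamp(passive, seed = 1))
  expect_true(all(rp$n_spikes == 0))
  # numeric-guard diagnostic on unstable configurations
  wild <- neuron_params(c_nF = 0.001)
  expect_error(simulate_current_clamp(wild, seed = 1), "unstable")
})
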