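test_that("biexponential decay fit recovers both taus and orders them", {
  t <- seq(0, 60, by = 0.05)
  set.seed(11)
  truth <- -5 * exp(-t / 2) - 5 * exp(-t / 20)
  y <- truth + rnorm(length(t), sd = 0.1)  # ~1 % of peak
  f <- fit_decay(tibble::tibble(t_ms = t, value = y), 0, 60)
  expect_equal(f$model, "biexponential")
  expect_equal(f$tau_fast, 2, tolerance = 0.05)
  expect_equal(f$tau_slow, 20, tolerance = 0.05)
  expect_lt(f$tau_fast, f$tau_slow)
})

test_that("clean single exponentials select the fallback model", {
  t <- seq(0, 50, by = 0.05)
  set.seed(12)
  y <- 3 * exp(-t / 5) + rnorm(length(t), sd = 0.03)
  f <- fit_decay(tibble::tibble(t_ms = t, value = y), 0, 50)
  expect_equal(f$model, "single_exponential")
  expect_equal(f$tau_fast, 5, tolerance = 0.02 * 5)
  expect_false(f$non_decaying)
})

test_that("constant traces are flagged non-decaying", {
  t <- seq(0, 50, by = 0.1)
  f <- fit_decay(tibble::tibble(t_ms = t, value = rep(-1.5, length(t))),
                 0, 50)
  expect_true(f$non_decaying)
  expect_equal(f$offset, -1.5)
  expect_equal(f$a_fast, 0)
  # pure noise must not earn decay components either
  set.seed(13)
  fn <- fit_decay(tibble::tibble(t_ms = t, value = rnorm(length(t))), 0, 50)
  expect_true(fn$non_decaying)
})

test_that("decay-fit window validation rejects bad inputs", {
  t <- seq(0, 50, by = 0.1)
  tr <- tibble::tibble(t_ms = t, value = exp(-t / 5))
  expect_error(fit_decay(tr, 10, 10), "t_start")
  expect_error(fit_decay(tr, 0, 2), "50 samples")
})

test_that("persistent fraction measures the late plateau", {
  t <- seq(0, 100, by = 0.05)
  # fully persistent current
  expect_equal(persistent_fraction(tibble::tibble(t_ms = t, value = -2)),
               1.0)
  # generative 10 % persistent current, step >> tau_slow
  p <- oracle_params(persistent_frac = 0.1)
  sw <- simulate_iv(p, protocol_preset("helix_iv"), noise_sd = 0, seed = 1)
  d <- dplyr::filter(sw, command == 0, epoch == "step")
  pf <- persistent_fraction(d, peak = d$value[1])
  # plateau = pf + (1-pf) h_inf(0), relative to the onset availability
  h0 <- steady_state_gates(p, -50)$h_inf
  expect_equal(pf, (0.1 + 0.9 * steady_state_gates(p, 0)$h_inf) /
                 (0.1 + 0.9 * h0), tolerance = 0.01)
  # fully inactivating current decays to ~0
  p0 <- oracle_params(persistent_frac = 0)
  sw0 <- simulate_iv(p0, protocol_preset("helix_iv"), noise_sd = 0, seed = 1)
  d0 <- dplyr::filter(sw0, command == 0, epoch == "step")
  expect_lt(abs(persistent_fraction(d0, peak = d0$value[1])), 0.01)
  # zero peak flagged undefined
  expect_warning(
    out <- persistent_fraction(tibble::tibble(t_ms = t, value = 0)), "peak")
  expect_true(is.na(out))
})

test_that("recovery fractions are scale-invariant and tau-sensitive", {
  p <- recovery_oracle_params(recovery_tau = 10)
  sw <- simulate_recovery(p, protocol_preset("helix_recovery"),
                          noise_sd = 0, seed = 1)
  rc <- recovery_fractions(sw, fit = TRUE)
  expect_equal(attr(rc, "fit")$tau, 10, tolerance = 0.05)
  # invariance under uniform rescaling of the current
  sw2 <- sw
  sw2$value <- sw2$value * 7.3
  rc2 <- recovery_fractions(sw2)
  expect_equal(rc$fraction, rc2$fraction, tolerance = 1e-12)
  # slowed recovery depresses every interpulse point
  slow <- apply_toxin(p, toxin_effect("Tch4", scale_recovery_tau = 3))
  rc3 <- recovery_fractions(simulate_recovery(
    slow, protocol_preset("helix_recovery"), noise_sd = 0, seed = 1))
  expect_true(all(rc3$fraction <= rc$fraction + 1e-9))
})

test_that("fold changes recover generative tau scalings on paired cells", {
  # instantaneous activation puts the peak at step onset, so the whole
  # step is a clean two-component decay
  p <- gating_params(tau_act = 0)
  proto <- protocol_preset("helix_iv")
  eff <- toxin_effect("venom", scale_tau_fast = 4, scale_tau_slow = 20)
  pt <- apply_toxin(p, eff)
  one <- function(par, s) {
    sw <- simulate_iv(par, proto, noise_sd = 0.01, seed = s)
    d <- dplyr::filter(sw, command == -10, epoch == "step")
    t0 <- min(d$t_ms)
    f <- fit_decay(d, t0, t0 + 199)
    tibble::tibble(cell_id = paste0("c", s %% 100),
                   tau_fast = f$tau_fast, tau_slow = f$tau_slow)
  }
  ctl <- dplyr::bind_rows(lapply(1:4, function(s) one(p, s)))
  trt <- dplyr::bind_rows(lapply(1:4, function(s) one(pt, s + 100)))
  fc <- fold_change(ctl, trt)
  expect_equal(fc$fold[fc$component == "tau_fast"], 4, tolerance = 0.1)
  expect_equal(fc$fold[fc$component == "tau_slow"], 20, tolerance = 0.15)
  # identical fits give unity fold change
  fc0 <- fold_change(ctl, ctl)
  expect_equal(fc0$fold, c(1, 1))
  expect_error(fold_change(ctl, trt[1:2, ]), "paired")
})

test_that("tau ordering is canonical regardless of starting guesses", {
  t <- seq(0, 60, by = 0.05)
  set.seed(14)
  y <- -4 * exp(-t / 18) - 6 * exp(-t / 1.2) + rnorm(length(t), sd = 0.05)
  f <- fit_decay(tibble::tibble(t_ms = t, value = y), 0, 60)
  expect_lt(f$tau_fast, f$tau_slow)
  expect_equal(f$tau_fast, 1.2, tolerance = 0.1)
  expect_equal(f$tau_slow, 18, tolerance = 0.1)
})

test_that("the voltage of maximal effect tracks the largest peak difference", {
  iv_c <- tibble::tibble(step_mV = c(-30, -20, -10), peak = c(-2, -5, -4))
  iv_t <- tibble::tibble(step_mV = c(-30, -20, -10), peak = c(-2, -1, -3.5))
  expect_equal(voltage_of_max_effect(iv_c, iv_t), -20)
  expect_equal(voltage_of_max_effect(iv_c, iv_t, override = -10), -10)
  expect_error(voltage_of_max_effect(iv_c,
                                     dplyr::mutate(iv_t, step_mV = 0:2)),
               "shared")
})
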