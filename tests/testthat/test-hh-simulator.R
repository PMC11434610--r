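test_that("gating rates match a hand-coded arithmetic oracle and are nonnegative", {
  # independent transcription of the rate formulas, kept separate from the
  # package's compiled implementation
  oracle_traub_n <- function(v) {
    c(alpha = 0.032 * (v + 52) / (1 - exp(-(v + 52) / 5)),
      beta = 0.5 * exp(-(v + 57) / 40))
  }
  oracle_classic_n <- function(v) {
    c(alpha = 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10)),
      beta = 0.125 * exp(-(v + 65) / 80))
  }
  expect_equal(gating_rates(-55, "n", "traub"), oracle_traub_n(-55),
               tolerance = 1e-12)
  expect_equal(gating_rates(-54, "n", "classic"), oracle_classic_n(-54),
               tolerance = 1e-12)
  for (v in c(-100, -50, 0, 50)) {
    for (g in c("m", "h", "n")) {
      r <- gating_rates(v, g)
      expect_gte(r[["alpha"]], 0)
      expect_gte(r[["beta"]], 0)
    }
  }
  expect_error(gating_rates(-50, "x"), "unknown gate")
})

test_that("removable singularities of the rate functions are handled", {
  # classic alpha_m has the 0/0 point exactly at v = -40
  near <- gating_rates(-40 + 1e-9, "m", "classic")[["alpha"]]
  at <- gating_rates(-40, "m", "classic")[["alpha"]]
  expect_equal(at, near, tolerance = 1e-6)
  expect_equal(at, 1, tolerance = 1e-6) # limit 0.1 * y with y = 10
})

test_that("h-gate steady state is the printed sigmoid", {
  expect_equal(gate_steady_state(-60, "h")[["inf"]], 0.5)
  expect_equal(gate_steady_state(-60 - 6.2, "h")[["inf"]],
               1 / (1 + exp(-1)))
})

test_that("state derivative equals the hand-computed current balance", {
  p <- default_params()
  st <- c(v = -50, m = 0.2, h = 0.6, n = 0.3)
  d <- hh_derivatives(st, p, stim = 5)
  iNa <- p$gNa_max * 0.2^3 * 0.6 * (-50 - p$vNa)
  iK <- p$gK_max * 0.3^4 * (-50 - p$vK)
  iL <- p$gL * (-50 - p$vL)
  expect_equal(d[["v"]], (5 - iNa - iK - iL) / p$C, tolerance = 1e-12)
  # gated-leak, first-power variant of the same balance
  p1 <- hh_params(k_gate_exponent = 1, leak_gated = TRUE)
  d1 <- hh_derivatives(st, p1, stim = 5)
  iK1 <- p1$gK_max * 0.3 * (-50 - p1$vK)
  iL1 <- p1$gL * 0.3 * (-50 - p1$vL)
  expect_equal(d1[["v"]], (5 - iNa - iK1 - iL1) / p1$C, tolerance = 1e-12)
})

test_that("gate derivatives keep [0,1] forward-invariant", {
  p <- default_params()
  for (v in c(-80, -50, 0)) {
    d0 <- hh_derivatives(c(v = v, m = 0, h = 0, n = 0), p)
    d1 <- hh_derivatives(c(v = v, m = 1, h = 1, n = 1), p)
    expect_true(all(d0[c("m", "h", "n")] >= 0))
    expect_true(all(d1[c("m", "h", "n")] <= 0))
  }
})

test_that("derivatives vanish at the resting fixed point", {
  p <- default_params()
  rest <- resting_state(p)
  d <- hh_derivatives(rest, p)
  expect_true(all(abs(d) < 1e-9))
})

test_that("conductance scaling is linear, identity at zero intensity", {
  expect_equal(conductance_scaling(conductance_modulation()),
               c(sK = 1, sNa = 1))
  for (I in c(0.5, 1, 2, 7)) {
    m1 <- conductance_modulation(beta_K = 0.3, intensity = I)
    m2 <- conductance_modulation(beta_K = 0.3, intensity = 2 * I)
    s1 <- conductance_scaling(m1); s2 <- conductance_scaling(m2)
    expect_equal(s2[["sK"]] - 1, 2 * (s1[["sK"]] - 1), tolerance = 1e-12)
    expect_equal(s1[["sNa"]], 1) # sodium unaffected by default
  }
  expect_error(conductance_modulation(beta_K = -2, intensity = 1),
               "negative conductance")
})

test_that("terahertz field waveform is a cosine with the stated frequency", {
  f <- thz_field(A = 2, nu = 36)
  expect_equal(thz_field_waveform(f, 0), 2)
  period <- 1 / (36e12)
  expect_equal(thz_field_waveform(f, period / 2), -2)
  expect_equal(thz_angular_frequency(f), 2 * pi * 36e12)
})

test_that("rest persists without stimulus and gates stay in [0,1]", {
  p <- default_params()
  rest <- resting_state(p)
  tr <- simulate_hh(p, protocol = constant_stimulus(0, 200), T = 200)
  expect_lt(max(abs(tr$v - rest[["v"]])), 1)
  for (g in c("m", "h", "n")) {
    expect_true(all(tr[[g]] >= 0 & tr[[g]] <= 1))
  }
  expect_length(tr$v, 200 / 0.01 + 1)
})

test_that("gating invariants hold under strong pulsed protocols", {
  p <- default_params()
  prot <- stimulus_protocol(data.frame(start = c(10, 120),
                                       duration = c(50, 60),
                                       amplitude = c(3, -1)))
  tr <- simulate_hh(p, protocol = prot, T = 250)
  for (g in c("m", "h", "n"))
    expect_true(all(tr[[g]] >= 0 & tr[[g]] <= 1))
  expect_true(all(is.finite(tr$v)))
})

test_that("enhanced potassium conductance suppresses firing", {
  p <- default_params()
  tr1 <- simulate_hh(p, mod_sK(1), constant_stimulus(0.3, 500), T = 500)
  tr2 <- simulate_hh(p, mod_sK(1.5), constant_stimulus(0.3, 500), T = 500)
  expect_lt(nrow(detect_spikes(tr2)), nrow(detect_spikes(tr1)))
})

test_that("spike times converge under step halving", {
  p <- default_params()
  run <- function(dt) {
    tr <- simulate_hh(p, protocol = constant_stimulus(1, 500), T = 500,
                      dt = dt)
    detect_spikes(tr)$peak_time
  }
  s1 <- run(0.01); s2 <- run(0.005)
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 0.05)
})

test_that("trajectory agrees with an adaptive independent integrator", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  rest <- resting_state(p)
  rhs <- function(t, y, parms) {
    names(y) <- c("v", "m", "h", "n")
    list(unname(hh_derivatives(y, p, stim = 1)))
  }
  times <- seq(0, 120, by = 0.01)
  sol <- deSolve::lsoda(unname(rest), times, rhs, NULL,
                        rtol = 1e-9, atol = 1e-9)
  ref <- make_trace(sol[, 2], dt = 0.01)
  tr <- simulate_hh(p, protocol = constant_stimulus(1, 120), T = 120)
  t_ref <- detect_spikes(ref)$peak_time
  t_rk <- detect_spikes(tr)$peak_time
  expect_equal(length(t_ref), length(t_rk))
  expect_lt(max(abs(t_ref - t_rk)), 0.05)
})

test_that("increasing sK hyperpolarizes the resting potential toward vK", {
  p <- default_params()
  v_rest <- vapply(c(1, 1.5, 2), function(s)
    resting_state(p, mod_sK(s))[["v"]], numeric(1))
  expect_true(all(diff(v_rest) < 0))
  expect_true(all(v_rest > p$vK))
})
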