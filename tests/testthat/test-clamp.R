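test_that("protocol presets reproduce the printed step structures", {
  kv <- make_protocol("kv")
  expect_equal(length(kv$step_levels), 21)
  expect_equal(kv$holding_v, -100)
  expect_equal(range(kv$step_levels), c(-70, 130))
  expect_equal(kv$step_duration, 100)

  nav <- make_protocol("nav")
  expect_equal(length(nav$step_levels), 8)
  expect_equal(nav$holding_v, -100)
  expect_equal(nav$pre_duration, 20)

  kleak <- make_protocol("kleak")
  expect_equal(kleak$holding_v, -70)
  expect_equal(range(kleak$step_levels), c(-120, -30))
  expect_equal(kleak$step_duration, 400)

  expect_error(make_protocol("kv", step_increment = 7), "divide")
})

test_that("clamp currents obey zero driving force and Ohm's law", {
  leak <- channel_leak(g = 0.3, E_rev = -90)
  ts <- run_voltage_clamp(leak, make_protocol("kleak"))
  step_i <- iv_curve(ts, "steady_state")
  expect_equal(step_i$i, 0.3 * (step_i$v - (-90)), tolerance = 1e-12)
  expect_equal(step_i$i[step_i$v == -90], 0)

  kv <- channel_kv(E_rev = -70)
  prot <- make_protocol("kv")
  ts2 <- run_voltage_clamp(kv, prot)
  # the step exactly at the reversal potential carries no step current
  on_step <- ts2$t >= ts2$step_onset
  expect_lt(max(abs(ts2$i[on_step, prot$step_levels == -70])), 1e-9)
})

test_that("Kv steady-state current matches the closed form", {
  kv <- channel_kv()
  ts <- run_voltage_clamp(kv, make_protocol("kv"))
  ivd <- iv_curve(ts, "steady_state")
  n_inf <- 1 / (1 + exp((kv$act_v_half - 30) / kv$act_k))
  expect_equal(ivd$i[ivd$v == 30],
               kv$g_max * n_inf^kv$kexp * (30 - kv$E_rev),
               tolerance = 1e-3)
})

test_that("peak extraction equals an independent scan, and scaled Kv steepens the I-V slope", {
  nav <- channel_nav()
  ts <- run_voltage_clamp(nav, make_protocol("nav"))
  pk <- iv_curve(ts, "peak")
  on_step <- ts$t >= ts$step_onset
  for (j in seq_along(ts$step_levels)) {
    col <- ts$i[on_step, j]
    expect_equal(pk$i[j], col[which.max(abs(col))])
  }

  kv1 <- run_voltage_clamp(channel_kv(), make_protocol("kv"))
  kv2 <- run_voltage_clamp(channel_kv(g_max = 36 * 1.5), make_protocol("kv"))
  s1 <- coef(lm(i ~ v, iv_curve(kv1, "steady_state")))[2]
  s2 <- coef(lm(i ~ v, iv_curve(kv2, "steady_state")))[2]
  expect_gt(s2, s1)
})

test_that("Boltzmann fits recover exact parameters and the midpoint property", {
  v <- seq(-80, 20, by = 5)
  y <- 1 / (1 + exp((-30 - v) / 5))
  fit <- fit_boltzmann(v, y, "activation")
  expect_equal(fit$v_half, -30, tolerance = 1e-6)
  expect_equal(fit$slope_k, 5, tolerance = 1e-6)
  expect_equal(fit$g_max, 1, tolerance = 1e-6)
  # fitted curve passes through half maximum at v_half
  at_half <- fit$g_max / (1 + exp((fit$v_half - fit$v_half) / fit$slope_k))
  expect_equal(at_half, fit$g_max / 2)

  yi <- 1 / (1 + exp((v - (-55)) / 6.2))
  fi <- fit_boltzmann(v, yi, "inactivation")
  expect_equal(fi$v_half, -55, tolerance = 1e-6)
  expect_equal(fi$slope_k, 6.2, tolerance = 1e-6)
})

test_that("noisy Boltzmann fits are unbiased at moderate noise", {
  v <- seq(-70, 30, length.out = 21)
  truth <- 1 / (1 + exp((-30 - v) / 5))
  set.seed(7)
  est <- t(replicate(60, {
    f <- fit_boltzmann(truth + rnorm(21, 0, 0.02), v = v, "activation")
    c(f$v_half, f$slope_k)
  }))
  expect_lt(abs(mean(est[, 1]) - (-30)), 1)
  expect_lt(abs(mean(est[, 2]) - 5), 0.5)
})

test_that("exponential tau regression recovers a known time constant", {
  t <- seq(0, 50, by = 0.1)
  y <- 2 + 5 * exp(-t / 7)
  f <- fit_exp_tau(t, y)
  expect_equal(f$tau, 7, tolerance = 1e-6)
  expect_equal(f$y_inf, 2, tolerance = 1e-6)
})

test_that("leak rule uses exactly the levels at or above -65 mV and recovers (g, E)", {
  ts <- gen_current_traces("kleak", channel_leak(g = 0.42, E_rev = -88))
  la <- leak_analysis(ts)
  expect_equal(la$levels_used, c(-60, -50, -40, -30))
  expect_equal(la$g_leak, 0.42, tolerance = 1e-9)
  expect_equal(la$E_rev, -88, tolerance = 1e-6)
  expect_error(leak_analysis(ts, v_min = -29), "insufficient")
})

test_that("noisy leak slope estimates are unbiased", {
  slopes <- vapply(1:50, function(s) {
    ts <- gen_current_traces("kleak", channel_leak(g = 0.42, E_rev = -88),
                             noise_sigma = 0.5, seed = 1000 + s)
    leak_analysis(ts)$g_leak
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.42), 4 * mc_se + 1e-4)
})

test_that("curve extraction is invariant to step-order permutation", {
  ts <- gen_current_traces("kleak", channel_leak(g = 0.3, E_rev = -90))
  perm <- sample(seq_along(ts$step_levels))
  ts_p <- ts
  ts_p$i <- ts$i[, perm]
  ts_p$step_levels <- ts$step_levels[perm]
  ts_p$protocol$step_levels <- ts$protocol$step_levels[perm]
  iv1 <- iv_curve(ts, "steady_state")
  iv2 <- iv_curve(ts_p, "steady_state")
  expect_equal(iv2[order(iv2$v), ], iv1[order(iv1$v), ],
               ignore_attr = TRUE)
  expect_equal(leak_analysis(ts_p)$g_leak, leak_analysis(ts)$g_leak)
})

test_that("full conductance-transform round trip recovers generator gating parameters", {
  kv <- channel_kv(act_v_half = -20, act_k = 12)
  ts <- run_voltage_clamp(kv, make_protocol("kv"))
  ivd <- iv_curve(ts, "steady_state")
  sel <- ivd$v != kv$E_rev
  g <- ivd$i[sel] / (ivd$v[sel] - kv$E_rev)
  fit <- fit_boltzmann(ivd$v[sel], g, "activation")
  expect_equal(fit$v_half, -20, tolerance = 0.05)
  expect_equal(fit$slope_k, 12, tolerance = 0.05)
  expect_equal(fit$g_max, kv$g_max, tolerance = 0.05)
})
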